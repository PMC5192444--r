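# Schemes and small datasets shared across test files.

riboswitch_scheme <- function() packaged_scheme("riboswitch")
propranolol_scheme <- function() packaged_scheme("propranolol")

# Minimal two-ordinal-block scheme (dosage/time) for crisping checks.
ordinal_scheme <- function() {
  coding_scheme(
    factor_block("dosage", c("D0", "D1", "D2", "D3"), "ordinal",
                 codes = c(0, 2, 4, 6)),
    factor_block("time", c("T0", "T1", "T2"), "ordinal", codes = c(0, 1, 6)))
}

# Full factorial design table for a scheme, r replicates per cell.
full_design <- function(scheme, replicates = 3L) {
  cells <- label_space(scheme)
  d <- cells[rep(seq_len(nrow(cells)), each = replicates), , drop = FALSE]
  d$replicate_id <- paste0("R", rep(seq_len(replicates), nrow(cells)))
  d$sample_id <- sprintf("S%03d", seq_len(nrow(d)))
  rownames(d) <- NULL
  d[c("sample_id", "replicate_id", setdiff(colnames(d),
                                           c("sample_id", "replicate_id")))]
}

# Essentially noise-free, linearly separable dataset for a scheme: each
# design cell sits on its own feature axis (one indicator feature per
# cell), so the encoded Y is an exact linear function of X and a PLS model
# can classify every block perfectly.
separable_dataset <- function(scheme, replicates = 3L, spacing = 50,
                              noise_sd = 1e-3, seed = 1L) {
  set.seed(seed)
  design <- full_design(scheme, replicates)
  factors <- setdiff(colnames(design), c("sample_id", "replicate_id"))
  key <- do.call(paste, c(design[factors], sep = "/"))
  cells <- unique(key)
  p <- length(cells)
  centre <- diag(spacing, p)
  X <- centre[match(key, cells), , drop = FALSE] +
    matrix(rnorm(nrow(design) * p, sd = noise_sd), nrow(design), p)
  dimnames(X) <- list(design$sample_id, sprintf("V%02d", seq_len(p)))
  list(X = X, design = design)
}
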