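#' Specify a synthetic factorial-design dataset
#'
#' Describes a ground-truth generative model for a samples x features table
#' with factorial structure: per-factor additive effects on a random subset
#' of features, optional pairwise interactions, and i.i.d. Gaussian noise.
#'
#' Each level of a *categorical* factor adds an independent shift to every
#' affected feature, drawn as N(0, (effect_size * noise_sd)^2) per
#' (level, feature) pair: `effect_size` is the typical per-feature level
#' shift in noise-standard-deviation units, the way a per-metabolite fold
#' change is usually quantified. An *ordinal* factor adds a per-feature
#' slope (same N(0, (effect_size * noise_sd)^2) scale) multiplied by the
#' level's standardised coded value -- a linear-in-code gradient.
#'
#' @param factors List of factor descriptions, each a list with `name`,
#'   `levels`, `type` (`"categorical"` or `"ordinal"`), optional `codes`
#'   (ordinal; defaults to `seq_along(levels)`), `effect_size`
#'   (noise-sd units; 0 means the factor does not touch the features) and
#'   `affected_fraction` (share of features carrying the effect).
#' @param n_features Number of feature columns.
#' @param replicates Biological replicates per design cell.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param interactions Optional list of interaction terms, each a list with
#'   `factors` (two factor names), `effect_size` and `affected_fraction`:
#'   every level combination of the pair gets its own random-direction
#'   shift.
#' @param cells Optional data frame of factor-level combinations for
#'   incomplete designs (one column per factor); default is the full
#'   factorial.
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(factors, n_features = 200L, replicates = 3L,
                        noise_sd = 1, interactions = NULL, cells = NULL) {
  stopifnot(length(factors) >= 1L, n_features >= 1L, replicates >= 1L)
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  nms <- character(0)
  for (f in factors) {
    for (k in c("name", "levels", "type", "effect_size", "affected_fraction"))
      if (is.null(f[[k]])) stop("factor description missing '", k, "'")
    if (!f$type %in% c("categorical", "ordinal"))
      stop("factor '", f$name, "': type must be categorical or ordinal")
    if (f$affected_fraction < 0 || f$affected_fraction > 1)
      stop("factor '", f$name, "': affected_fraction must be in [0, 1]")
    if (f$effect_size < 0)
      stop("factor '", f$name, "': effect_size must be >= 0")
    nms <- c(nms, f$name)
  }
  if (anyDuplicated(nms)) stop("factor names must be unique")
  if (!is.null(cells)) {
    if (!setequal(colnames(cells), nms))
      stop("cells columns must match the factor names")
    cells <- cells[nms]
    if (anyDuplicated(do.call(paste, c(cells, sep = "\r"))))
      stop("cells must be unique")
    for (f in factors) {
      bad <- setdiff(unique(as.character(cells[[f$name]])), f$levels)
      if (length(bad))
        stop("cells use unknown level(s) of '", f$name, "': ",
             paste(bad, collapse = ", "))
    }
  }
  for (ia in interactions) {
    if (length(ia$factors) != 2L || !all(ia$factors %in% nms))
      stop("each interaction needs two known factor names")
  }
  structure(list(factors = factors, n_features = as.integer(n_features),
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 interactions = interactions, cells = cells),
            class = "effect_spec")
}

#' Generate a synthetic dataset from an effect specification
#'
#' Fully reproducible from `seed`: the design table, the affected-feature
#' masks, the effect directions and the noise are all drawn from the seeded
#' stream.
#'
#' @param spec An [effect_spec()].
#' @param seed Integer seed.
#' @return Object of class `synthetic_dataset`: `features` (matrix with
#'   sample ids as row names), `design` (data frame with `sample_id`,
#'   `replicate_id` and one column per factor), `masks` (named list of
#'   affected feature indices per factor), `spec` and `seed`.
#' @export
generate <- function(spec, seed) {
  stopifnot(inherits(spec, "effect_spec"))
  set.seed(as.integer(seed))
  p <- spec$n_features
  cells <- spec$cells
  if (is.null(cells)) {
    cells <- expand.grid(lapply(spec$factors, `[[`, "levels"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    names(cells) <- vapply(spec$factors, `[[`, character(1L), "name")
  }
  r <- spec$replicates
  design <- cells[rep(seq_len(nrow(cells)), each = r), , drop = FALSE]
  design$replicate_id <- paste0("R", rep(seq_len(r), nrow(cells)))
  design$sample_id <- sprintf("S%03d", seq_len(nrow(design)))
  rownames(design) <- NULL
  design <- design[c("sample_id", "replicate_id",
                     setdiff(colnames(design), c("sample_id", "replicate_id")))]
  n <- nrow(design)

  shift <- matrix(0, n, p)
  masks <- list()
  for (f in spec$factors) {
    n_aff <- if (f$effect_size > 0) round(f$affected_fraction * p) else 0L
    mask <- if (n_aff > 0) sort(sample.int(p, n_aff)) else integer(0)
    masks[[f$name]] <- mask
    if (n_aff == 0L) next
    L <- length(f$levels)
    mag <- f$effect_size * spec$noise_sd
    li <- match(as.character(design[[f$name]]), f$levels)
    if (f$type == "categorical") {
      shifts <- matrix(stats::rnorm(L * n_aff, sd = mag), L, n_aff)
      shift[, mask] <- shift[, mask] + shifts[li, , drop = FALSE]
    } else {
      codes <- if (!is.null(f$codes)) as.numeric(f$codes)
               else seq_along(f$levels)
      ct <- (codes - mean(codes)) / stats::sd(codes)
      slope <- stats::rnorm(n_aff, sd = mag)
      shift[, mask] <- shift[, mask] + ct[li] %o% slope
    }
  }
  for (ia in spec$interactions) {
    n_aff <- if (ia$effect_size > 0) round(ia$affected_fraction * p) else 0L
    if (n_aff == 0L) next
    mask <- sort(sample.int(p, n_aff))
    combo <- paste(as.character(design[[ia$factors[1L]]]),
                   as.character(design[[ia$factors[2L]]]), sep = "\r")
    uc <- unique(combo)
    shifts <- matrix(stats::rnorm(length(uc) * n_aff,
                                  sd = ia$effect_size * spec$noise_sd),
                     length(uc), n_aff)
    ci <- match(combo, uc)
    shift[, mask] <- shift[, mask] + shifts[ci, , drop = FALSE]
  }

  X <- shift + matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
  dimnames(X) <- list(design$sample_id, sprintf("V%03d", seq_len(p)))
  structure(list(features = X, design = design, masks = masks,
                 spec = spec, seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d samples x %d features, %d factor(s), seed %d\n",
              nrow(x$features), ncol(x$features), length(x$masks), x$seed))
  invisible(x)
}

#' Preset: two-factor full factorial with a strong and a weak factor
#'
#' Emulates the shape of a 5-strain x 4-inducer-condition GC-MS study with
#' 3 biological replicates per cell (60 samples, 200 features): a strong
#' 5-level factor (effect 2.5 sd on 20% of features) and a weak 4-level
#' factor (effect 0.8 sd on 20% of features), unit noise. Pair with
#' `packaged_scheme("riboswitch")`.
#'
#' @param seed Integer seed.
#' @return A `synthetic_dataset`.
#' @export
riboswitch_like <- function(seed) {
  spec <- effect_spec(
    factors = list(
      list(name = "strain",
           levels = c("wild-type", "PET", "EGFP", "iL3EGFP", "iL3PET"),
           type = "categorical", effect_size = 2.5, affected_fraction = 0.2),
      list(name = "inducer",
           levels = c("control", "IPTG", "IPTG+PPDA", "PPDA"),
           type = "categorical", effect_size = 0.8, affected_fraction = 0.2)),
    n_features = 200L, replicates = 3L, noise_sd = 1)
  generate(spec, seed)
}

#' Preset: incomplete three-factor design with an ordinal dosage gradient
#'
#' Emulates a 3-strain x 4-dosage x 3-time-point exposure study with 4
#' biological replicates, where the first time point exists only at the
#' control dosage (samples are taken immediately before the compound is
#' added): 27 populated cells, 108 samples, 200 features. The dosage and
#' time factors act as linear-in-code gradients under the 0/2/4/6 and
#' 0/1/6 codings. Pair with `packaged_scheme("propranolol")`.
#'
#' @param seed Integer seed.
#' @return A `synthetic_dataset`.
#' @export
propranolol_like <- function(seed) {
  full <- expand.grid(strain = c("S1", "S2", "S3"),
                      dosage = c("D0", "D1", "D2", "D3"),
                      time = c("T0", "T1", "T2"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- full[!(full$time == "T0" & full$dosage != "D0"), , drop = FALSE]
  spec <- effect_spec(
    factors = list(
      list(name = "strain", levels = c("S1", "S2", "S3"),
           type = "categorical", effect_size = 2.0, affected_fraction = 0.2),
      list(name = "dosage", levels = c("D0", "D1", "D2", "D3"),
           type = "ordinal", codes = c(0, 2, 4, 6),
           effect_size = 1.5, affected_fraction = 0.2),
      list(name = "time", levels = c("T0", "T1", "T2"),
           type = "ordinal", codes = c(0, 1, 6),
           effect_size = 1.0, affected_fraction = 0.2)),
    n_features = 200L, replicates = 4L, noise_sd = 1, cells = cells)
  generate(spec, seed)
}
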