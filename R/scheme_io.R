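#' Read a coding scheme from a YAML config
#'
#' The config has a top-level `blocks:` list, each entry with keys `name`,
#' `type` (`categorical` or `ordinal`), `levels`, and `codes` (a pair
#' `off, on` for categorical blocks, one value per level for ordinal ones).
#' Three packaged schemes mirror classic GC-MS study designs:
#' `riboswitch.yaml` (two 0/1 one-of-k blocks: 5 strains, 4 inducer
#' conditions), `propranolol.yaml` (0/6 strain block plus ordinal dosage
#' \{0,2,4,6\} and time \{0,1,6\} columns) and `propranolol_even_time.yaml`
#' (time recoded evenly as \{0,3,6\}).
#'
#' @param path Path to a YAML file.
#' @return A [coding_scheme()].
#' @examples
#' sc <- read_coding_scheme(
#'   system.file("extdata", "riboswitch.yaml", package = "structpls"))
#' sc$width
#' @export
read_coding_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$blocks)) stop("scheme config has no 'blocks' entry: ", path)
  blocks <- lapply(cfg$blocks, function(b) {
    for (k in c("name", "type", "levels"))
      if (is.null(b[[k]])) stop("scheme block missing key '", k, "'")
    factor_block(b$name, as.character(unlist(b$levels)), b$type,
                 codes = if (!is.null(b$codes)) as.numeric(unlist(b$codes)))
  })
  coding_scheme(blocks)
}

#' Write a coding scheme to a YAML config
#'
#' @param scheme A [coding_scheme()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coding_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "coding_scheme"))
  cfg <- list(blocks = lapply(unname(scheme$blocks), function(b) {
    list(name = b$name, type = b$type, levels = as.list(b$levels),
         codes = as.list(b$codes))
  }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Packaged coding-scheme fixtures
#'
#' Convenience loader for the schemes shipped under `extdata`.
#'
#' @param name One of `"riboswitch"`, `"propranolol"`,
#'   `"propranolol_even_time"`.
#' @return A [coding_scheme()].
#' @export
packaged_scheme <- function(name = c("riboswitch", "propranolol",
                                     "propranolol_even_time")) {
  name <- match.arg(name)
  read_coding_scheme(system.file("extdata", paste0(name, ".yaml"),
                                 package = "structpls", mustWork = TRUE))
}
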