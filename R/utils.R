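#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a locally seeded RNG
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions never perturb user randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Structured log message to stderr
#'
#' Emitted only when `options(denovobirth.verbose = TRUE)` is set (or
#' `force = TRUE`), keeping pipeline runs quiet by default.
#'
#' @param ... Message parts, pasted together.
#' @param force Emit regardless of the verbosity option.
#' @return Invisibly, the message text.
#' @export
dn_log <- function(..., force = FALSE) {
  msg <- paste0(...)
  if (force || isTRUE(getOption("denovobirth.verbose", FALSE))) {
    message("[denovobirth] ", msg)
  }
  invisible(msg)
}

#' Read a YAML configuration file
#'
#' @param path Path to a YAML file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

# stop codons in the standard nuclear code
STOP_CODONS <- c("TAA", "TAG", "TGA")

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_stop_codon <- function(codon) toupper(codon) %in% STOP_CODONS
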