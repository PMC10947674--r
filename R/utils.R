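# Internal helpers shared across modules.

#' Derive a child seed from a base seed
#'
#' Deterministic mixing of a base seed and an index into a new seed in
#' `[0, 2^31 - 2]`, so every stage of the pipeline (population generation,
#' parameter draws, per-year random streams, replicates) gets its own
#' reproducible stream from a single user-supplied integer.
#'
#' @param seed base integer seed.
#' @param k integer stream index (may be a vector).
#' @return integer seed(s).
#' @export
derive_seed <- function(seed, k) {
  m <- 2147483399
  s <- as.numeric(seed) %% m
  x <- (s * 40014 + as.numeric(k) * 40692 + 12211) %% m
  as.integer(x)
}

# Standard Gumbel(0,1) draws; used for taste shocks in the labour module.
rgumbel <- function(n) -log(-log(stats::runif(n)))

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Recursively overwrite entries of a nested default list with entries of
# `override`, refusing keys that do not exist in the defaults. `path` is used
# for error messages only.
merge_config <- function(defaults, override, path = "") {
  if (is.null(override)) return(defaults)
  stopifnot(is.list(defaults))
  if (!is.list(override)) {
    stop("configuration error: expected a mapping at '", path, "'", call. = FALSE)
  }
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) {
    stop("configuration error: unknown key(s) ",
         paste0("'", path, bad, "'", collapse = ", "), call. = FALSE)
  }
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]],
                                     path = paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- override[[nm]]
    }
  }
  defaults
}

stop_domain <- function(...) stop(..., call. = FALSE)

# Sum `x` within integer groups 1..n_groups, returning a full-length vector
# (zero for empty groups).
group_sum <- function(x, group, n_groups) {
  out <- numeric(n_groups)
  if (length(x) == 0) return(out)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
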