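# shared internal helpers

ACGT <- c("A", "C", "G", "T")

complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_ambiguous_pair <- function(a1, a2) {
  a1 == complement(a2)
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize a constant vector", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Derive a deterministic per-stage seed from a global seed
#'
#' Expands one pipeline seed into independent substream seeds so that, for
#' example, adding permutations to one cell never perturbs the simulation
#' draws of another stage. The result is always a valid 32-bit seed.
#'
#' @param seed integer global seed.
#' @param stage character label of the stage or cell.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(paste(stage, collapse = "/")) *
             seq_along(utf8ToInt(paste(stage, collapse = "/"))))
  as.integer((abs(as.numeric(seed)) * 48271 + 7907 * h) %% 2147483629)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
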