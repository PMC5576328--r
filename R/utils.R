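#' Derive a child seed from a master seed
#'
#' Analyses with several stochastic stages (rarefaction, permutation tests,
#' Monte-Carlo Procrustes) use one master seed; each stage consumes a child
#' seed derived deterministically from the master seed and a stage name, so
#' adding or reordering stages never silently changes another stage's draws.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31)`.
#' @export
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(paste(stage, collapse = "/"))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer((abs(master) * 2654435761 + h) %% 2147483647)
}

# Multivariate hypergeometric draw: subsample `size` units without
# replacement from a pool whose category totals are `counts`.
rmvhyper_counts <- function(counts, size) {
  counts <- as.integer(counts)
  n <- sum(counts)
  if (size > n) stop("cannot subsample ", size, " from a pool of ", n)
  if (size == n) return(counts)
  drawn <- sample.int(n, size)
  tabulate(findInterval(drawn - 1L, cumsum(c(0L, counts)), left.open = FALSE),
           nbins = length(counts))
}

# findInterval-based tabulation above maps unit index -> category; keep a
# slower reference formulation available for clarity in tests.
rmvhyper_counts_ref <- function(counts, size) {
  pool <- rep.int(seq_along(counts), counts)
  tabulate(sample(pool, size), nbins = length(counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
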