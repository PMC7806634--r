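#' Derive a reproducible sub-seed from a global seed and a stage tag
#'
#' All randomised stages draw their seed from the single run seed through
#' this mixer, so stages are decoupled (re-running one stage does not
#' perturb another) while the whole run stays reproducible.
#'
#' @param seed Integer global seed.
#' @param tag Character stage tag.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) %% 1000003L) * 2011L + (h %% 999983L)) %% .Machine$integer.max
}

# dense rank, largest value gets rank 1, ties share a rank
dense_rank_desc <- function(x) {
  match(x, sort(unique(x), decreasing = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mito_genes <- function(symbols) grepl("^MT-", symbols)
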