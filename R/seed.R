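#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from a single master seed; each
#' stage/subject draws from its own substream so that, e.g., adding a subject
#' does not perturb another subject's noise realization.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels naming the substream
#'   (e.g. `"bold"`, subject index).
#' @return an integer seed in `[0, 2^31 - 2]`, a deterministic function of
#'   `master` and the labels.
#' @export
substream_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labels)) h <- (h * 31 + ch) %% 2147483629
  as.integer((as.numeric(master) %% 2147483629 + h) %% 2147483629)
}

with_substream <- function(master, ..., expr) {
  seed <- substream_seed(master, ...)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
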