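`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Deterministic per-stage seeds let pipeline stages use independent random
#' streams while remaining reproducible from a single master seed.  The stage
#' name is folded into an integer with a Knuth-style multiplicative hash, so
#' any two stage names give unrelated seeds.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) {
    ## keep the accumulator < 2^53 so double arithmetic stays exact
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer((h + (as.numeric(master) %% 2147483647) * 2654435) %% 2147483647)
}

## Clamp FST into [0, 1 - eps] so T = -log(1 - FST) stays finite.
clamp_fst <- function(fst, eps = 1e-9) {
  pmin(pmax(fst, 0), 1 - eps)
}

## writer used everywhere so tabular outputs are byte-stable
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
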