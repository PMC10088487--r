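# Internal helpers shared across modules.

# Run `expr` under a local RNG stream without disturbing the caller's state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

#' Standard 10-20 / 10-10 channel labels for synthetic montages
#'
#' The first 8 labels form a compact frontal-to-occipital test montage; the
#' full set provides the 37 positions of the recording montage the synthetic
#' generator can mirror.
#'
#' @param n number of channels (at most 37).
#' @return character vector of `n` electrode labels.
#' @export
montage_labels <- function(n) {
  labs <- c("Fp1", "Fp2", "F3", "F4", "Cz", "Pz", "O1", "O2",
            "F7", "F8", "T3", "T4", "T5", "T6", "C3", "C4", "P3", "P4",
            "Fz", "Oz", "AF3", "AF4", "FC1", "FC2", "FC5", "FC6",
            "CP1", "CP2", "CP5", "CP6", "PO3", "PO4", "FT9", "FT10",
            "TP9", "TP10", "POz")
  if (n > length(labs))
    stop("montage supports at most ", length(labs), " channels")
  labs[seq_len(n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
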