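#' Derive a reproducible child seed from a root seed and a category label
#'
#' Analysis runs draw one root seed; every bootstrap within the run uses a
#' child seed obtained by hashing the category label into the root. Results
#' for a category are therefore independent of the order in which categories
#' are processed.
#'
#' The hash is a 31-multiplier polynomial rolling hash of the UTF-8 bytes of
#' `key`, reduced modulo 2^31 - 1 at every step so the arithmetic stays exact
#' in double precision.
#'
#' @param root_seed Integer root seed for the whole run.
#' @param key Character scalar identifying the category
#'   (e.g. `"grain_yield|ZT-DSR(dry)|<none>"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1L, "grain_yield|CT-DSR(wet)|<none>")
#' @export
derive_seed <- function(root_seed, key) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L,
            is.character(key), length(key) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- as.double(root_seed) %% m
  for (b in utf8ToInt(enc2utf8(key))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

# shared column-presence check with a schema error naming the column
check_columns <- function(df, required, what = "input") {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "ricemeta_schema_error")
  }
  invisible(df)
}

# weighted mean with positive weights; no NA handling by design
wmean <- function(x, w) sum(w * x) / sum(w)
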