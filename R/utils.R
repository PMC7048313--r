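#' @importFrom rlang %||% abort warn inform .data
#' @import tibble
#' @importFrom dplyr arrange bind_rows count desc distinct filter group_by
#'   inner_join left_join mutate n rename row_number select semi_join summarise
#'   ungroup anti_join
#' @importFrom stats phyper p.adjust cor setNames
#' @importFrom utils head
NULL

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# global stream is untouched.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1], got %s.",
                  name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Encode/decode ordered node pairs (a, b), a != b, into a single key for fast
# set operations on arcs. Node ids are 0-based and < 2^26 here, so the key
# fits exactly in a double.
arc_key <- function(from, to, n) {
  as.numeric(from) * n + as.numeric(to)
}
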