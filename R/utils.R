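#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   distinct left_join inner_join bind_rows n n_distinct across all_of rename
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif setNames p.adjust phyper
#' @importFrom utils head tail
NULL

# Evaluate `code` under a pinned, restorable RNG state. All synthetic-data
# generators run through this so fixtures are pure functions of (params, seed).
# Generator pin: Mersenne-Twister / Inversion / Rejection (recorded in truth
# output).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

rng_spec <- function() {
  list(kind = "Mersenne-Twister", normal_kind = "Inversion",
       sample_kind = "Rejection")
}

# Derive k reproducible child seeds from one parent seed (kept < 2^31).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

check_condition <- function(condition) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% c("pre", "post")) {
    abort("`condition` must be \"pre\" or \"post\".")
  }
  condition
}

# Read a delimited text file as all-character columns so that per-row
# validation can report precise line numbers (line 1 is the header).
read_table_chr <- function(path, required, delim = "\t") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- if (identical(delim, "ws")) {
    readr::read_table(path, col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE)
  } else {
    readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE, trim_ws = TRUE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("File %s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  df
}

# Parse a character column as numeric/integer, aborting with the 1-based file
# line of the first bad row (header = line 1).
parse_num_col <- function(x, col, path, integer = FALSE) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(x) > 0 && any(is.na(x))) bad <- sort(unique(c(bad, which(is.na(x)))))
  if (length(bad) > 0L) {
    abort(sprintf("File %s, line %d: column '%s' has non-numeric value '%s'.",
                  path, bad[1] + 1L, col, x[bad[1]]))
  }
  if (integer) {
    if (any(v != round(v))) {
      i <- which(v != round(v))[1]
      abort(sprintf("File %s, line %d: column '%s' must be an integer (got '%s').",
                    path, i + 1L, col, x[i]))
    }
    v <- as.integer(round(v))
  }
  v
}
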