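#' Combine HBS classifications into a long set table
#'
#' @param ... `hbs_result` objects (or a single list of them), each carrying
#'   sample/condition provenance.
#' @return Tibble `sample_id`, `condition`, `node` with one row per HBS
#'   member.
#' @export
hbs_set_table <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "hbs_result")) {
    xs <- xs[[1]]
  }
  purrr::map_dfr(xs, function(h) {
    tibble(
      sample_id = attr(h, "sample_id", exact = TRUE) %||% NA_character_,
      condition = attr(h, "condition", exact = TRUE) %||% NA_character_,
      node = hbs_members(h)
    )
  })
}

as_hbs_sets <- function(hbs) {
  lapply(split(hbs$node, hbs$sample_id), function(v) sort(unique(v)))
}

#' Intersect HBS sets across samples within one condition
#'
#' Computes, for one treatment condition, the per-sample HBS set sizes, every
#' pairwise intersection (size and sorted members) and the full k-way common
#' set. Member lists are always sorted lexicographically and the report is
#' invariant (up to labeling) under permutation of the input sets.
#'
#' @param hbs Tibble `sample_id`, `condition`, `node` (see [hbs_set_table()]).
#' @param condition Condition to analyse; may be omitted when `hbs` holds a
#'   single condition. Mixing conditions without naming one is an error.
#' @return An `hbs_intersection` object with elements `condition`, `sizes`,
#'   `pairwise` (tibble with a `members` list-column), `kway_members`,
#'   `kway_n`.
#' @export
intersect_hbs <- function(hbs, condition = NULL) {
  if (is.null(condition)) {
    conds <- unique(hbs$condition)
    if (length(conds) != 1L) {
      abort("`hbs` mixes conditions; name the `condition` to intersect.")
    }
    condition <- conds
  } else {
    check_condition(condition)
    hbs <- filter(hbs, .data$condition == !!condition)
  }
  sets <- as_hbs_sets(hbs)
  if (length(sets) < 2L) {
    abort(sprintf("Need HBS sets from >= 2 samples for condition '%s' (got %d).",
                  condition, length(sets)))
  }
  ids <- names(sets)
  sizes <- tibble(sample_id = ids, n_hbs = lengths(sets)[ids])
  pairs <- utils::combn(ids, 2L)
  pairwise <- tibble(
    sample_a = pairs[1, ],
    sample_b = pairs[2, ],
    members = purrr::map2(pairs[1, ], pairs[2, ],
                          ~ sort(intersect(sets[[.x]], sets[[.y]])))
  ) |>
    mutate(n_common = lengths(.data$members)) |>
    select("sample_a", "sample_b", "n_common", "members")
  kway <- sort(Reduce(intersect, sets))
  structure(
    list(condition = condition, sizes = sizes, pairwise = pairwise,
         kway_members = kway, kway_n = length(kway)),
    class = "hbs_intersection"
  )
}

#' @export
print.hbs_intersection <- function(x, ...) {
  cat(sprintf("<hbs_intersection> condition '%s', %d samples\n",
              x$condition, nrow(x$sizes)))
  cat("Per-sample HBS sizes:\n")
  print(x$sizes)
  cat("Pairwise common HBS:\n")
  print(select(x$pairwise, -"members"))
  cat(sprintf("%d-way common HBS: %d\n", nrow(x$sizes), x$kway_n))
  invisible(x)
}

#' @method tidy hbs_intersection
#' @export
tidy.hbs_intersection <- function(x, ...) {
  mutate(x$pairwise, condition = x$condition, .before = 1)
}

#' @method glance hbs_intersection
#' @export
glance.hbs_intersection <- function(x, ...) {
  tibble(condition = x$condition, n_samples = nrow(x$sizes),
         kway_common = x$kway_n)
}

#' Overlap of HBS sets between treatment conditions
#'
#' For matched pre/post samples, computes the pre-vs-post HBS overlap per
#' sample and the single global intersection over every set of both
#' conditions. Samples must be matched: each sample id has to appear in both
#' conditions.
#'
#' @param hbs Tibble `sample_id`, `condition`, `node` covering both
#'   conditions.
#' @return A `condition_overlap` object: `per_sample` tibble (`sample_id`,
#'   `n_common`, `members` list-column) and `global_members`/`global_n` over
#'   all sets.
#' @export
cross_condition_overlap <- function(hbs) {
  pre <- filter(hbs, .data$condition == "pre")
  post <- filter(hbs, .data$condition == "post")
  pre_sets <- as_hbs_sets(pre)
  post_sets <- as_hbs_sets(post)
  unmatched <- c(setdiff(names(pre_sets), names(post_sets)),
                 setdiff(names(post_sets), names(pre_sets)))
  if (length(unmatched) > 0L) {
    abort(sprintf("Sample(s) present in only one condition: %s",
                  paste(sort(unique(unmatched)), collapse = ", ")))
  }
  if (length(pre_sets) == 0L) abort("No samples to overlap.")
  ids <- sort(names(pre_sets))
  per_sample <- tibble(
    sample_id = ids,
    members = purrr::map(ids, ~ sort(intersect(pre_sets[[.x]], post_sets[[.x]])))
  ) |>
    mutate(n_common = lengths(.data$members)) |>
    select("sample_id", "n_common", "members")
  global <- sort(Reduce(intersect, c(pre_sets, post_sets)))
  structure(
    list(per_sample = per_sample, global_members = global,
         global_n = length(global)),
    class = "condition_overlap"
  )
}

#' @export
print.condition_overlap <- function(x, ...) {
  cat("<condition_overlap> pre vs post HBS overlap\n")
  print(select(x$per_sample, -"members"))
  cat(sprintf("Global intersection over all sets: %d\n", x$global_n))
  invisible(x)
}

#' @method tidy condition_overlap
#' @export
tidy.condition_overlap <- function(x, ...) {
  x$per_sample
}
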