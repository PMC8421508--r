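#' Standard output age groups
#'
#' The five standard age groups used in the harmonized output: 0-14, 15-64,
#' 65-74, 75-84 and the open-ended 85+. The grouping was chosen for the
#' epidemiology of acute mortality shocks (detail at old ages, broad adult
#' group) and is the default target of [split_age_groups()]; any other
#' non-overlapping, nested grouping built with [age_group_table()] can be
#' substituted.
#'
#' @return A tibble with columns `age_start`, `age_interval` (years; `Inf`
#'   for the open-ended group) and `age_label`.
#' @export
#' @examples
#' stmf_age_groups()
stmf_age_groups <- function() {
  age_group_table(starts = c(0, 15, 65, 75, 85),
                  intervals = c(15, 50, 10, 10, Inf))
}

#' Build an age-group definition table
#'
#' @param starts Integer lower bounds of the age intervals, strictly
#'   increasing, starting at 0.
#' @param intervals Interval widths in years; the last may be `Inf` for an
#'   open-ended terminal group. Groups must tile the age axis without gaps
#'   or overlaps.
#' @return A tibble with `age_start`, `age_interval`, `age_label`.
#' @export
age_group_table <- function(starts, intervals) {
  stopifnot(length(starts) == length(intervals), length(starts) >= 1)
  if (is.unsorted(starts, strictly = TRUE)) {
    rlang::abort("age group starts must be strictly increasing")
  }
  ends <- starts + intervals
  if (length(starts) > 1 && any(ends[-length(ends)] != starts[-1])) {
    rlang::abort("age groups must tile the age axis (end of one = start of next)")
  }
  tibble::tibble(
    age_start = as.numeric(starts),
    age_interval = as.numeric(intervals),
    age_label = age_label(starts, intervals)
  )
}

#' Format an age interval as a label like "15-64" or "85+"
#' @param age_start,age_interval Numeric vectors (interval `Inf` = open).
#' @return Character vector of labels.
#' @export
age_label <- function(age_start, age_interval) {
  ifelse(is.infinite(age_interval),
         paste0(age_start, "+"),
         paste0(age_start, "-", age_start + age_interval - 1))
}

# TRUE where [x, x+a) is contained in [s, s+b); open-ended handled via Inf
nests_in <- function(x, a, s, b) {
  x >= s & (x + a) <= (s + b)
}

# For each target group, index of the source interval that contains it,
# or an error if a target straddles / escapes the sources.
match_targets_to_sources <- function(targets, sources) {
  idx <- purrr::map_int(seq_len(nrow(targets)), function(i) {
    hit <- which(nests_in(targets$age_start[i], targets$age_interval[i],
                          sources$age_start, sources$age_interval))
    if (length(hit) != 1L) {
      rlang::abort(sprintf(
        "target age group %s does not nest in exactly one source interval (sources: %s)",
        age_label(targets$age_start[i], targets$age_interval[i]),
        paste(age_label(sources$age_start, sources$age_interval), collapse = ", ")))
    }
    hit
  })
  idx
}
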