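#' Define a questionnaire scale
#'
#' A `scale_spec` records the per-construct metadata needed to simulate,
#' score, and range-check a multi-item Likert scale: item count, the
#' response range shared by all items, and which items are reverse coded.
#' The attainable score range is implied:
#' `[n_items * item_min, n_items * item_max]`.
#'
#' @param name scale label (used as a column-name prefix, `<name>_<item>`).
#' @param n_items positive integer number of items.
#' @param item_min,item_max integer response bounds of a single item.
#' @param reverse_items integer indices (in `1:n_items`) of reverse-coded
#'   items; scoring maps a response `v` to `item_min + item_max - v`.
#' @return an object of class `scale_spec`.
#' @examples
#' scale_spec("gse", n_items = 10, item_min = 1, item_max = 4)
#' @export
scale_spec <- function(name, n_items, item_min, item_max,
                       reverse_items = integer(0)) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  n_items <- as.integer(n_items)
  item_min <- as.integer(item_min)
  item_max <- as.integer(item_max)
  reverse_items <- as.integer(reverse_items)
  if (n_items < 1) stop("n_items must be a positive integer")
  if (item_max <= item_min) stop("item_max must exceed item_min")
  if (length(reverse_items) &&
      (any(reverse_items < 1) || any(reverse_items > n_items)))
    stop("reverse_items must be indices in 1:n_items")
  structure(list(name = name, n_items = n_items, item_min = item_min,
                 item_max = item_max, reverse_items = sort(unique(reverse_items)),
                 score_range = c(n_items * item_min, n_items * item_max)),
            class = "scale_spec")
}

#' @export
print.scale_spec <- function(x, ...) {
  cat(sprintf("<scale_spec> %s: %d items in [%d, %d], score range [%d, %d]",
              x$name, x$n_items, x$item_min, x$item_max,
              x$score_range[1], x$score_range[2]))
  if (length(x$reverse_items))
    cat(", reverse items:", paste(x$reverse_items, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Default battery of twelve questionnaire scales
#'
#' The twelve constructs of the dissociation study this package emulates:
#' felt-sense-of-anomaly dissociation plus eleven candidate mechanisms,
#' with each scale's item count and response range chosen so the summed
#' score ranges match the published instruments (e.g. 35 items scored
#' 0-4 give the 0-140 dissociation total; 10 items scored 1-4 give the
#' 10-40 self-efficacy total).  Which items are reverse coded is not part
#' of the published scale ranges; the reverse sets used here are synthetic
#' choices that exercise reverse scoring.
#'
#' @return a named list of [scale_spec] objects.
#' @export
default_scale_specs <- function() {
  specs <- list(
    scale_spec("cefsa", 35, 0, 4),                       # dissociation (FSA), 0-140
    scale_spec("cad",   13, 0, 4),                       # cognitive appraisals, 0-52
    scale_spec("rtd",    6, 0, 4),                       # responses to dissociation, 0-24
    scale_spec("ais",   30, 1, 6),                       # affect intolerance, 30-180
    scale_spec("asi",   18, 0, 4),                       # anxiety sensitivity, 0-72
    scale_spec("atc",   20, 1, 4, reverse_items = seq(2, 20, by = 4)),  # attentional control, 20-80
    scale_spec("bvs",    4, 0, 10),                      # body vigilance, 0-40
    scale_spec("gse",   10, 1, 4),                       # general self-efficacy, 10-40
    scale_spec("mes",   11, 1, 6),                       # negative meta-emotion, 11-66
    scale_spec("oaq",   11, 1, 5, reverse_items = 5L),   # alexithymia, 11-55
    scale_spec("ptq",   15, 0, 4),                       # perseverative thinking, 0-60
    scale_spec("ovw",    8, 0, 4)                        # beliefs about being overwhelmed, 0-32
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

as_scale_spec_list <- function(specs) {
  if (inherits(specs, "scale_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, TRUE, "scale_spec")))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}
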