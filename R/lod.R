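#' Detection call for a single signal reading
#'
#' A fragment counts as detected when its electropherogram peak reaches the
#' detection bound (default 0.1 RFU, inclusive).
#'
#' @param rfu signal strength, relative fluorescence units (>= 0).
#' @param threshold detection bound, RFU (> 0).
#' @return logical, `rfu >= threshold` (vectorised).
#' @examples
#' is_detected(c(0.1, 0.099, 0))  # TRUE FALSE FALSE
#' @export
is_detected <- function(rfu, threshold = 0.1) {
  stopifnot(is.numeric(rfu), is.numeric(threshold), threshold > 0)
  if (any(rfu < 0, na.rm = TRUE)) stop("rfu must be >= 0", call. = FALSE)
  rfu >= threshold
}

check_readings <- function(readings) {
  req <- c("target", "copies", "condition", "replicate", "rfu")
  missing_cols <- setdiff(req, names(readings))
  if (length(missing_cols)) {
    stop("readings are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cond_ok <- c("single_target", "target_mix", "single_plus_background",
               "mix_plus_background")
  bad <- setdiff(unique(readings$condition), cond_ok)
  if (length(bad)) {
    stop("unknown condition(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(cond_ok, collapse = "/"), ")", call. = FALSE)
  }
  if (any(readings$rfu < 0)) stop("rfu must be >= 0", call. = FALSE)
  if (any(readings$copies < 0)) stop("copies must be >= 0", call. = FALSE)
  readings
}

#' Limit of detection from a replicated sensitivity grid
#'
#' The LOD is the smallest tested template copy number at which every
#' replicate is detected, with the additional stability requirement that no
#' higher tested level shows a failure (a "stable reaction"): a failure above
#' an otherwise clean level leaves the LOD undefined rather than silently
#' accepting a non-monotone grid. Levels below the LOD where only some
#' replicates were detected are reported as the unstable range.
#'
#' @param readings data frame with columns `target`, `copies`, `condition`,
#'   `replicate`, `rfu` (see [read_readings()]).
#' @param target,condition the grid slice to analyse.
#' @param threshold detection bound, RFU.
#' @return object of class `lod_result`: `target`, `condition`, `lod_copies`
#'   (NA when undefined), `unstable_range` (copy levels with partial
#'   detection below the LOD), and `levels` (per-level detection summary:
#'   `copies`, `n`, `n_detected`, `full`).
#' @examples
#' g <- expand.grid(target = "t1", copies = c(7, 20, 100), replicate = 1:3,
#'                  condition = "single_target", stringsAsFactors = FALSE)
#' g$rfu <- ifelse(g$copies >= 20, 0.5, c(0.3, 0.2, 0.05))
#' lod_from_grid(g, "t1", "single_target")
#' @export
lod_from_grid <- function(readings, target, condition, threshold = 0.1) {
  readings <- check_readings(readings)
  slice <- readings[readings$target == target &
                      readings$condition == condition, , drop = FALSE]
  if (nrow(slice) == 0L) {
    stop(sprintf("no readings for target '%s' under condition '%s'",
                 target, condition), call. = FALSE)
  }
  det <- is_detected(slice$rfu, threshold)
  lv <- sort(unique(slice$copies))
  n <- vapply(lv, function(l) sum(slice$copies == l), integer(1))
  nd <- vapply(lv, function(l) sum(det[slice$copies == l]), integer(1))
  full <- nd == n
  # stable from the top: largest suffix of levels that are all fully detected
  lod <- NA_real_
  if (any(full)) {
    suffix_ok <- rev(cumprod(rev(full))) == 1
    if (any(suffix_ok)) lod <- lv[which(suffix_ok)[1L]]
  }
  partial <- lv[nd > 0L & nd < n]
  unstable <- if (is.na(lod)) partial else partial[partial < lod]
  structure(list(
    target = target, condition = condition,
    lod_copies = lod, unstable_range = unstable,
    levels = data.frame(copies = lv, n = n, n_detected = nd, full = full)
  ), class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("LOD for '%s' (%s): %s copies/reaction\n", x$target,
              x$condition,
              if (is.na(x$lod_copies)) "undefined" else
                format(x$lod_copies)))
  if (length(x$unstable_range)) {
    cat("  partial detection at:", paste(x$unstable_range, collapse = ", "),
        "copies\n")
  }
  invisible(x)
}

#' Limits of detection for every target x condition slice of a grid
#'
#' @inheritParams lod_from_grid
#' @return data frame: `target`, `condition`, `lod_copies` (NA when
#'   undefined), `unstable` (comma-separated partial-detection levels).
#' @export
lod_table <- function(readings, threshold = 0.1) {
  readings <- check_readings(readings)
  combos <- unique(readings[, c("target", "condition")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    r <- lod_from_grid(readings, combos$target[i], combos$condition[i],
                       threshold)
    data.frame(target = r$target, condition = r$condition,
               lod_copies = r$lod_copies,
               unstable = paste(r$unstable_range, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarise per-target signal strength at one standardised input
#'
#' @inheritParams lod_from_grid
#' @param copies template copies per reaction at which to summarise.
#' @param targets targets that must all be present (default: every target in
#'   `readings`); a missing one raises a coverage error naming it.
#' @param stat `"median"` (robust to one failed lane) or `"mean"`.
#' @return data frame: `target`, `rfu` (the summary), `rfu_min`, `rfu_max`,
#'   `n`.
#' @export
summarize_signals <- function(readings, copies, condition, targets = NULL,
                              stat = c("median", "mean")) {
  stat <- match.arg(stat)
  readings <- check_readings(readings)
  if (is.null(targets)) targets <- unique(readings$target)
  slice <- readings[readings$copies == copies &
                      readings$condition == condition, , drop = FALSE]
  absent <- setdiff(targets, slice$target)
  if (length(absent)) {
    stop(sprintf("no readings at %g copies under '%s' for target(s): %s",
                 copies, condition, paste(absent, collapse = ", ")),
         call. = FALSE)
  }
  f <- if (stat == "median") stats::median else mean
  rows <- lapply(targets, function(t) {
    r <- slice$rfu[slice$target == t]
    data.frame(target = t, rfu = f(r), rfu_min = min(r), rfu_max = max(r),
               n = length(r), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Lay out a full factorial sensitivity experiment
#'
#' Emits the bench-ready table of reactions needed to measure per-target
#' sensitivity: every target of the panel at every template copy level,
#' under each condition, replicated. Background conditions carry the stated
#' mass of non-amplifiable, non-target DNA (simulating e.g. consumer DNA in
#' a gut-content extract).
#'
#' @param panel a [primer_panel()] (multiplex pairs define the targets) or a
#'   character vector of target names.
#' @param copy_levels template copies per reaction to test.
#' @param conditions subset of `single_target`, `target_mix`,
#'   `single_plus_background`, `mix_plus_background`.
#' @param replicates reactions per cell (>= 1).
#' @param background_ng non-target DNA added in the `*_background`
#'   conditions, ng.
#' @return data frame: `target`, `copies`, `condition`, `replicate`,
#'   `background_ng`.
#' @export
design_sensitivity_grid <- function(panel, copy_levels,
                                    conditions = c("single_target",
                                                   "target_mix",
                                                   "single_plus_background",
                                                   "mix_plus_background"),
                                    replicates = 3L, background_ng = 300) {
  targets <- if (inherits(panel, "primer_panel")) {
    panel$target[panel$in_multiplex]
  } else as.character(panel)
  stopifnot(length(targets) >= 1L, length(copy_levels) >= 1L,
            replicates >= 1L)
  conditions <- match.arg(conditions, several.ok = TRUE)
  g <- expand.grid(replicate = seq_len(replicates), condition = conditions,
                   copies = copy_levels, target = targets,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("target", "copies", "condition", "replicate")]
  g$background_ng <- ifelse(grepl("background", g$condition), background_ng, 0)
  rownames(g) <- NULL
  g
}
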