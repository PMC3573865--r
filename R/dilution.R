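#' Volume-indexed pipetting-error model
#'
#' Pipetting imprecision is the dominant error source when standardising
#' template copy numbers, and it grows sharply at small volumes. The model is
#' a table of (volume, CV) nodes with linear interpolation between them and no
#' extrapolation outside the range; the CV must be non-increasing in volume.
#' The shipped default (1 uL: 8%, 5 uL: 3%, 10 uL: 1%, 100 uL: 0.5%) is a
#' conservative reading of typical air-displacement pipette performance and is
#' fully overridable.
#'
#' @param volumes_ul pipetted volumes (uL), strictly increasing.
#' @param cvs coefficient of variation (fraction) at each volume,
#'   non-increasing.
#' @param min_pipettable_volume smallest volume (uL) a plan may ask for.
#' @return object of class `pipetting_error_model`.
#' @examples
#' m <- pipetting_error_model()
#' cv_at_volume(m, 10)   # 0.01 at a table node
#' cv_at_volume(m, 7.5)  # interpolated
#' @export
pipetting_error_model <- function(volumes_ul = c(1, 5, 10, 100),
                                  cvs = c(0.08, 0.03, 0.01, 0.005),
                                  min_pipettable_volume = 1) {
  stopifnot(is.numeric(volumes_ul), is.numeric(cvs),
            length(volumes_ul) == length(cvs), length(volumes_ul) >= 1,
            all(volumes_ul > 0), all(cvs >= 0),
            min_pipettable_volume > 0)
  if (is.unsorted(volumes_ul, strictly = TRUE)) {
    stop("volumes_ul must be strictly increasing", call. = FALSE)
  }
  if (any(diff(cvs) > 0)) {
    stop("CV must be non-increasing in volume", call. = FALSE)
  }
  structure(list(volumes_ul = volumes_ul, cvs = cvs,
                 min_pipettable_volume = min_pipettable_volume),
            class = "pipetting_error_model")
}

#' @rdname pipetting_error_model
#' @param model a `pipetting_error_model`.
#' @param volume_ul volume(s) to look up, uL; must lie within the table range
#'   (no extrapolation).
#' @export
cv_at_volume <- function(model, volume_ul) {
  stopifnot(inherits(model, "pipetting_error_model"))
  rng <- range(model$volumes_ul)
  out <- which(volume_ul < rng[1] | volume_ul > rng[2])
  if (length(out)) {
    stop(sprintf(
      "volume %g uL outside the error model's table range [%g, %g] (no extrapolation)",
      volume_ul[out[1L]], rng[1], rng[2]), call. = FALSE)
  }
  if (length(model$volumes_ul) == 1L) {
    return(rep(model$cvs, length(volume_ul)))
  }
  stats::approx(model$volumes_ul, model$cvs, xout = volume_ul,
                method = "linear", ties = "ordered")$y
}

#' One serial-dilution step
#'
#' @param aliquot_ul volume of source transferred (uL, > 0).
#' @param diluent_ul volume of diluent added (uL, >= 0).
#' @return one-row data frame with `aliquot_ul`, `diluent_ul` and the exact
#'   dilution `factor` `(aliquot + diluent) / aliquot`.
#' @examples
#' dilution_step(10, 90)  # a 1:10 step
#' @export
dilution_step <- function(aliquot_ul, diluent_ul) {
  stopifnot(is.numeric(aliquot_ul), is.numeric(diluent_ul),
            length(aliquot_ul) == length(diluent_ul))
  if (any(aliquot_ul <= 0)) stop("aliquot_ul must be > 0", call. = FALSE)
  if (any(diluent_ul < 0)) stop("diluent_ul must be >= 0", call. = FALSE)
  data.frame(aliquot_ul = aliquot_ul, diluent_ul = diluent_ul,
             factor = (aliquot_ul + diluent_ul) / aliquot_ul)
}

#' Total dilution factor of a step series
#'
#' The factors multiply: three 1:10 steps make a 1:1000 dilution. Order of
#' steps does not change the total.
#'
#' @param steps data frame of steps as built by [dilution_step()] (rows may
#'   be concatenated with `rbind`).
#' @return the product of the per-step factors.
#' @examples
#' total_factor(dilution_step(c(10, 10, 10), c(90, 90, 90)))  # 1000
#' @export
total_factor <- function(steps) {
  steps <- as_steps(steps)
  if (nrow(steps) == 0L) stop("empty step list", call. = FALSE)
  prod(steps$factor)
}

as_steps <- function(steps) {
  if (inherits(steps, "dilution_plan")) return(steps$steps)
  stopifnot(is.data.frame(steps),
            all(c("aliquot_ul", "diluent_ul", "factor") %in% names(steps)))
  steps
}

#' Propagate pipetting error across dilution steps
#'
#' Each step's CV is looked up from the error model at the step's aliquot
#' volume (the small, critical transfer; diluent can be delivered in several
#' accurate pushes and is not range-checked). Steps are independent, so the
#' total CV combines in quadrature: `sqrt(sum(cv_i^2))`. This is what makes
#' several small steps beat one large one — a 1:1000 in one go forces a tiny
#' aliquot with a large CV, while three 1:10 steps each pipette a comfortable
#' volume.
#'
#' @param steps data frame of dilution steps (or a `dilution_plan`).
#' @param error_model a [pipetting_error_model()].
#' @return total coefficient of variation (fraction).
#' @examples
#' propagate_cv(dilution_step(c(10, 10, 10), c(90, 90, 90)))  # sqrt(3)*0.01
#' propagate_cv(dilution_step(1, 999))                        # 0.08
#' @export
propagate_cv <- function(steps, error_model = pipetting_error_model()) {
  steps <- as_steps(steps)
  if (nrow(steps) == 0L) return(0)
  sqrt(sum(cv_at_volume(error_model, steps$aliquot_ul)^2))
}

#' Plan a stepwise serial dilution to a target copy number
#'
#' Finds the plan with the fewest steps whose factors are all at most
#' `max_step_factor` and whose product equals `source_copies / target_copies`.
#' The minimal step count is `ceiling(log(ratio) / log(max_step_factor))`;
#' the plan uses full `max_step_factor` steps followed by one smaller
#' remainder step (smallest factor last, so the largest dilutions act on the
#' most concentrated material). Every step transfers `step_volume` uL of the
#' previous tube into `step_volume * (factor - 1)` uL of diluent.
#'
#' @param source_copies stock concentration, copies/uL.
#' @param target_copies desired concentration, copies/uL
#'   (`0 < target <= source`).
#' @param max_step_factor largest admissible per-step factor (> 1).
#' @param step_volume aliquot transferred at each step, uL.
#' @param error_model a [pipetting_error_model()].
#' @return object of class `dilution_plan`: `steps` (data frame with
#'   `aliquot_ul`, `diluent_ul`, `factor`, `resulting_copies_per_ul`,
#'   `step_cv`), `source_copies`, `final_copies`, `total_factor`, `total_cv`,
#'   and a `note` reminding the bench to pre-wet tips.
#' @examples
#' plan_serial_dilution(10000, 10)  # 3 x 1:10
#' plan_serial_dilution(10000, 5)   # 10, 10, 10, 2
#' @export
plan_serial_dilution <- function(source_copies, target_copies,
                                 max_step_factor = 10, step_volume = 10,
                                 error_model = pipetting_error_model()) {
  stopifnot(is.numeric(source_copies), is.numeric(target_copies),
            length(source_copies) == 1L, length(target_copies) == 1L)
  if (!(target_copies > 0)) stop("target_copies must be > 0", call. = FALSE)
  if (target_copies > source_copies * (1 + 1e-12)) {
    stop("target_copies exceeds source_copies: dilution cannot concentrate",
         call. = FALSE)
  }
  if (!(max_step_factor > 1)) stop("max_step_factor must be > 1", call. = FALSE)
  if (step_volume < error_model$min_pipettable_volume) {
    stop(sprintf(
      "step_volume %g uL is below the minimum pipettable volume %g uL",
      step_volume, error_model$min_pipettable_volume), call. = FALSE)
  }

  ratio <- source_copies / target_copies
  if (abs(ratio - 1) <= 1e-9) {
    plan <- structure(list(
      steps = dilution_step(numeric(0), numeric(0)),
      source_copies = source_copies, final_copies = source_copies,
      total_factor = 1, total_cv = 0,
      note = "no dilution needed"), class = "dilution_plan")
    return(plan)
  }

  # fewest steps: k full-factor steps, then a remainder r in (1, max_factor]
  k <- floor(log(ratio) / log(max_step_factor) + 1e-9)
  r <- ratio / max_step_factor^k
  factors <- if (r <= 1 + 1e-9) rep(max_step_factor, k) else
    c(rep(max_step_factor, k), r)

  steps <- dilution_step(rep(step_volume, length(factors)),
                         step_volume * (factors - 1))
  steps$resulting_copies_per_ul <- source_copies / cumprod(steps$factor)
  steps$step_cv <- cv_at_volume(error_model, steps$aliquot_ul)
  tf <- prod(steps$factor)
  structure(list(
    steps = steps,
    source_copies = source_copies,
    final_copies = source_copies / tf,
    total_factor = tf,
    total_cv = propagate_cv(steps, error_model),
    note = "pre-wet the pipette tip before each transfer"),
    class = "dilution_plan")
}

#' @export
print.dilution_plan <- function(x, ...) {
  cat(sprintf(
    "Dilution plan: %.4g -> %.4g copies/uL (total factor %.6g, %d step%s, total CV %.2f%%)\n",
    x$source_copies, x$final_copies, x$total_factor, nrow(x$steps),
    if (nrow(x$steps) == 1L) "" else "s", 100 * x$total_cv))
  if (nrow(x$steps)) {
    print(format(x$steps, digits = 4), row.names = TRUE)
  }
  cat("Note:", x$note, "\n")
  invisible(x)
}

#' Compare two dilution plans achieving the same total factor
#'
#' @param a,b `dilution_plan` objects with equal total factors (relative
#'   tolerance `tol`).
#' @param error_model a [pipetting_error_model()] used to (re)compute both
#'   plans' propagated CVs.
#' @param tol relative tolerance for the total-factor equality check.
#' @return list with `winner` (`"a"`, `"b"` or `"equivalent"`), `cv_a`,
#'   `cv_b`, and `cv_difference` (`cv_a - cv_b`).
#' @examples
#' three <- plan_serial_dilution(1e6, 1e3)
#' one <- plan_serial_dilution(1e6, 1e3, max_step_factor = 1000,
#'                             step_volume = 1)
#' compare_plans(three, one)
#' @export
compare_plans <- function(a, b, error_model = pipetting_error_model(),
                          tol = 1e-9) {
  stopifnot(inherits(a, "dilution_plan"), inherits(b, "dilution_plan"))
  if (abs(a$total_factor - b$total_factor) >
      tol * max(a$total_factor, b$total_factor)) {
    stop(sprintf("plans are not comparable: total factors %.6g vs %.6g",
                 a$total_factor, b$total_factor), call. = FALSE)
  }
  cv_a <- propagate_cv(a$steps, error_model)
  cv_b <- propagate_cv(b$steps, error_model)
  winner <- if (isTRUE(all.equal(cv_a, cv_b))) "equivalent" else
    if (cv_a < cv_b) "a" else "b"
  list(winner = winner, cv_a = cv_a, cv_b = cv_b,
       cv_difference = cv_a - cv_b)
}
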