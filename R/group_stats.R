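# Study-level statistics: pooled-variance t tests with significance stars,
# orientation-class summaries, and the percentage endpoints.

#' Significance stars at the conventional thresholds
#'
#' Strict inequalities: `p < 0.05` one star up to `p < 0.0001` four stars;
#' `p = 0.05` exactly is `ns`.
#'
#' @param p p-value(s) in [0, 1].
#' @return Character vector in `{"ns", "*", "**", "***", "****"}`.
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 1e-2, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Two-group comparison by unpaired Student's t test
#'
#' Pooled-variance (Student) two-sided t test by default, matching the
#' convention of reporting mean difference with its standard error and
#' significance stars; Welch's correction is available behind a flag. With
#' zero pooled variance and unequal means the comparison is degenerate:
#' `p = 0` with `degenerate = TRUE`.
#'
#' @param a,b numeric vectors (n >= 2 each, finite values).
#' @param welch use Welch's unequal-variance test instead of the pooled
#'   test.
#' @return One-row data.frame: `n_a`, `n_b`, `mean_a`, `mean_b`, `sem_a`,
#'   `sem_b`, `mean_difference` (a minus b), `se_difference`,
#'   `t_statistic`, `degrees_of_freedom`, `p_two_sided`, `stars`,
#'   `degenerate`.
#' @examples
#' compare_groups(c(1, 2, 3, 4, 5), c(3, 4, 5, 6, 7))
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b),
            all(is.finite(a)), all(is.finite(b)))
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("both groups need n >= 2", call. = FALSE)
  ma <- mean(a); mb <- mean(b)
  pooled_var <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  degenerate <- FALSE
  if (pooled_var == 0 && var(a) == 0 && var(b) == 0 && ma != mb) {
    # identical constants within groups, different between: infinitely
    # significant under the model; flagged rather than hidden
    degenerate <- TRUE
    tt <- list(statistic = sign(ma - mb) * Inf,
               parameter = na + nb - 2, p.value = 0)
    sed <- 0
  } else {
    tt <- t.test(a, b, var.equal = !welch)
    sed <- if (welch) sqrt(var(a) / na + var(b) / nb)
           else sqrt(pooled_var * (1 / na + 1 / nb))
  }
  sem <- function(x) sd(x) / sqrt(length(x))
  data.frame(
    n_a = na, n_b = nb, mean_a = ma, mean_b = mb,
    sem_a = sem(a), sem_b = sem(b),
    mean_difference = ma - mb, se_difference = sed,
    t_statistic = unname(tt$statistic),
    degrees_of_freedom = unname(tt$parameter),
    p_two_sided = tt$p.value,
    stars = significance_stars(tt$p.value),
    degenerate = degenerate
  )
}

#' Orientation-class summary of a nucleus table
#'
#' Class fractions over all records (undefined included in
#' `fraction_undefined`); `mean_cos2phi` excludes undefined (near-circular)
#' objects, whose major-axis angle is meaningless.
#'
#' @param records data.frame with columns `cos2phi` and `orientation_class`,
#'   e.g. from [measure_nuclei()].
#' @return One-row data.frame: `n`, `n_oriented`, `mean_cos2phi`,
#'   `fraction_perpendicular`, `fraction_parallel`, `fraction_oblique`,
#'   `fraction_undefined`.
#' @export
orientation_summary <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("cos2phi", "orientation_class") %in% names(records)))
  if (!nrow(records)) stop("empty record table", call. = FALSE)
  cls <- as.character(records$orientation_class)
  n <- nrow(records)
  oriented <- cls != "undefined"
  data.frame(
    n = n,
    n_oriented = sum(oriented),
    mean_cos2phi = if (any(oriented)) mean(records$cos2phi[oriented])
                   else NA_real_,
    fraction_perpendicular = mean(cls == "perpendicular"),
    fraction_parallel = mean(cls == "parallel"),
    fraction_oblique = mean(cls == "oblique"),
    fraction_undefined = mean(cls == "undefined")
  )
}

#' Detachment percentage
#'
#' Percentage of cells remaining attached relative to the initial count.
#'
#' @param n_initial initial cell count (> 0).
#' @param n_remaining attached cells after the challenge
#'   (0 <= n_remaining <= n_initial).
#' @return Percentage in [0, 100].
#' @examples
#' detachment_percent(200, 70)  # 35
#' @export
detachment_percent <- function(n_initial, n_remaining) {
  stopifnot(is.numeric(n_initial), is.numeric(n_remaining),
            n_initial > 0, n_remaining >= 0)
  if (any(n_remaining > n_initial))
    stop("n_remaining exceeds n_initial", call. = FALSE)
  100 * n_remaining / n_initial
}

#' Wound-closure percentage
#'
#' `100 * (area_0h - area_t) / area_0h`: the standard scratch-assay closure
#' definition. A widening wound gives a negative value, returned with a
#' warning rather than an error so batch runs surface it.
#'
#' @param area_0h wound area at time 0 (> 0), any consistent unit.
#' @param area_t wound area at the later time point.
#' @return Percentage (<= 100; negative if the wound widened).
#' @examples
#' wound_closure_percent(1000, 600)  # 40
#' @export
wound_closure_percent <- function(area_0h, area_t) {
  stopifnot(is.numeric(area_0h), is.numeric(area_t), area_t >= 0)
  if (any(area_0h <= 0)) stop("area_0h must be positive", call. = FALSE)
  wc <- 100 * (area_0h - area_t) / area_0h
  if (any(wc < 0))
    warning("negative closure: wound widened between time points",
            call. = FALSE)
  wc
}
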