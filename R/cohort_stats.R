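HVC_CLASSES <- c("HM", "HL", "VM", "VL", "CM", "CL")

#' Parse a cohort/defect table
#'
#' Reads a CSV with columns `participant, sex, age, tooth, hvc` — one row
#' per implantation site, participants repeating across rows. Ridge
#' deficiencies are classed by the HVC scheme (horizontal / vertical /
#' combination, each medium or large). Tooth positions use FDI two-digit
#' notation.
#'
#' @param path CSV file path.
#' @return a data.frame of validated `DefectRecord` rows.
#' @export
parse_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "sex", "age", "tooth", "hvc")
  if (!all(need %in% names(df)))
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) return(df[, need])
  for (r in seq_len(nrow(df))) {
    row <- df[r, ]
    if (any(is.na(row[need])) || any(row[need] == ""))
      stop("missing field in cohort table row ", r)
    if (!row$sex %in% c("M", "F"))
      stop("invalid sex in cohort table row ", r, ": ", row$sex)
    if (!is.finite(row$age) || row$age <= 18)
      stop("age must be > 18 (inclusion criterion) in row ", r)
    q <- row$tooth %/% 10; p <- row$tooth %% 10
    if (!(q %in% 1:4 && p %in% 1:8))
      stop("non-FDI tooth position in cohort table row ", r, ": ", row$tooth)
    if (!row$hvc %in% HVC_CLASSES)
      stop("unknown HVC class in cohort table row ", r, ": ", row$hvc)
  }
  df$participant <- as.integer(df$participant)
  df$tooth <- as.integer(df$tooth)
  df[, need]
}

#' Cohort demographic and defect summaries
#'
#' Participant-level tallies (sex, age, tooth-gap size) and site-level HVC
#' class counts. Age moments use the n-1 standard deviation.
#'
#' @param records data.frame from [parse_cohort_table()].
#' @return list with `n_participants`, `n_sites`, `sex_counts`,
#'   `gap_size_counts` (sites per participant), `hvc_counts`, `age` (mean,
#'   sd, median, min, max).
#' @export
cohort_summary <- function(records) {
  if (nrow(records) == 0) stop("empty cohort")
  per <- records[!duplicated(records$participant), ]
  gap <- table(table(records$participant))
  ages <- per$age
  list(
    n_participants = nrow(per),
    n_sites = nrow(records),
    sex_counts = c(M = sum(per$sex == "M"), F = sum(per$sex == "F")),
    gap_size_counts = stats::setNames(as.integer(gap),
                                      paste0(names(gap), "_tooth")),
    hvc_counts = vapply(HVC_CLASSES, function(h) sum(records$hvc == h),
                        integer(1)),
    age = descriptive(ages)
  )
}

#' Descriptive statistics (mean, sd, median, min, max)
#'
#' Mean and n-1 standard deviation, median (midpoint average for even n),
#' and range — the descriptive battery of longitudinal volumetric tables.
#' The sd is reported as `NA` for a single observation.
#'
#' @param values numeric vector, length >= 1.
#' @return named list.
#' @export
descriptive <- function(values) {
  if (length(values) < 1) stop("descriptive() needs at least one value")
  list(n = length(values), mean = mean(values),
       sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
       median = stats::median(values),
       min = min(values), max = max(values))
}

## exact null distribution of W+ for signed ranks r (average ranks allowed):
## enumerate all 2^m sign assignments
wilcoxon_enumerate_p <- function(r, w_obs) {
  m <- length(r)
  ## distribution over subset sums of r
  sums <- 0
  for (ri in r) sums <- c(sums, sums + ri)
  eps <- 1e-9
  p_le <- mean(sums <= w_obs + eps)
  p_ge <- mean(sums >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided test of paired differences, with the classical zero-handling
#' rule (zero differences dropped) and average ranks for ties. For m <= 15
#' nonzero pairs the p-value comes from full enumeration of the 2^m
#' sign-assignment null; beyond that, a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max largest m handled by exact enumeration (default 15).
#' @return list with `method`, `statistic` (W+, sum of positive signed
#'   ranks), `p_value`, `n` (nonzero pairs), `sidedness`, `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 15) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    warning("all differences are zero; degenerate test")
    return(list(method = "wilcoxon_signed_rank", statistic = 0,
                p_value = 1, n = 0L, sidedness = "two.sided", exact = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (m <= exact_max) {
    p <- wilcoxon_enumerate_p(r, w)
    exact <- TRUE
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(ties^3 - ties) / 48
    cc <- sign(w - mu) * 0.5
    z <- (w - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(method = "wilcoxon_signed_rank", statistic = w, p_value = p,
       n = m, sidedness = "two.sided", exact = exact)
}

#' Spearman rank-order correlation
#'
#' rho is the Pearson correlation of average ranks. The p-value is computed
#' by exact permutation for n <= 8 and by the t-approximation with n-2
#' degrees of freedom otherwise; two-sided throughout.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param exact_max largest n handled by exact permutation (default 8).
#' @return list with `method`, `statistic` (rho), `p_value`, `n`,
#'   `sidedness`, `exact`.
#' @export
spearman_rho <- function(x, y, exact_max = 8) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("spearman_rho needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    exact <- TRUE
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
    exact <- FALSE
  }
  list(method = "spearman_rho", statistic = rho, p_value = p, n = n,
       sidedness = "two.sided", exact = exact)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      rest <- sub[r, ]
      rest <- ifelse(rest >= pos, rest + 1L, rest)
      out[row, ] <- c(pos, rest)
      row <- row + 1
    }
  }
  out
}

#' Paired-design sample size from a standardized effect
#'
#' Smallest n whose two-sided paired t-test (equivalently a one-sample test
#' of the differences) achieves the requested power at effect size dz, via
#' the noncentral-t power function
#' `power(n) = P(|T| > t_{1-alpha/2, n-1})` with noncentrality `dz * sqrt(n)`.
#'
#' @param dz Cohen's dz (paired standardized effect), > 0.
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80).
#' @return smallest integer n >= 2 reaching the target power.
#' @export
paired_sample_size <- function(dz, alpha = 0.05, power = 0.80) {
  if (dz <= 0 || alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("invalid power specification")
  pw <- function(n) {
    tc <- stats::qt(1 - alpha / 2, df = n - 1)
    ncp <- dz * sqrt(n)
    stats::pt(-tc, df = n - 1, ncp = ncp) +
      1 - stats::pt(tc, df = n - 1, ncp = ncp)
  }
  n <- 2
  while (pw(n) < power && n < 1e6) n <- n + 1
  n
}
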