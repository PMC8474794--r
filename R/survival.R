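#' Clinical follow-up table
#'
#' Validates a per-patient clinical table.  Required columns: `sample_id`,
#' `time` (follow-up, months, > 0) and `event` (1 = event, 0 = censored).
#' Recognised optional columns: `endpoint` (DMFS/RFS/PFS), `er`
#' (`pos`/`neg`/`unknown`), `ln` (likewise), `grade` (1/2/3/`unknown`),
#' `age_gt50` and `size_gt20mm` (logical), `subtype`.
#'
#' @param df a data.frame.
#' @return the validated data.frame with class `clinical_table`.
#' @export
clinical_table <- function(df) {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  if (any(!is.finite(df$time)) || any(df$time <= 0))
    stop("follow-up times must be finite and > 0")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  class(df) <- unique(c("clinical_table", class(df)))
  df
}

#' Read a clinical table from TSV
#'
#' Expects at least columns `sample_id`, `time` (or `time_months`) and
#' `event`.
#'
#' @param path TSV path.
#' @return a [clinical_table()].
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("time_months" %in% names(df) && !"time" %in% names(df))
    names(df)[names(df) == "time_months"] <- "time"
  clinical_table(df)
}

#' Administrative follow-up cut-off
#'
#' Truncates follow-up at a fixed horizon (typically 120 months): patients
#' with time strictly beyond the cut-off are censored at the cut-off; an
#' event occurring exactly at the cut-off is retained as an event.
#'
#' @param ct a [clinical_table()].
#' @param cutoff horizon in the same units as `time` (> 0).
#' @return the truncated [clinical_table()].
#' @export
apply_followup_cutoff <- function(ct, cutoff) {
  stopifnot(cutoff > 0)
  over <- ct$time > cutoff
  ct$event[over] <- 0
  ct$time[over] <- cutoff
  ct
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return a data.frame with one row per distinct observed time:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv` (the survivor
#'   function just after `time`); `surv` is non-increasing and starts
#'   from S(0) = 1.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
  tt <- sort(unique(times))
  n_risk <- vapply(tt, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(times == t & events == 1), numeric(1))
  n_censor <- vapply(tt, function(t) sum(times == t & events == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = tt, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, surv = surv)
}

#' Survivor probability at given times
#'
#' Right-continuous evaluation of a [km_curve()] estimate.
#'
#' @param km a data.frame from [km_curve()].
#' @param t times at which to evaluate.
#' @return S(t) for each `t`.
#' @export
km_surv_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  ifelse(idx == 0, 1, km$surv[pmax(idx, 1)])
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square across two or more
#' groups, with `groups - 1` degrees of freedom and an upper-tail p-value.
#'
#' @param times follow-up times.
#' @param events event indicators (1/0).
#' @param group group labels (two or more non-empty groups).
#' @return a list of class `logrank_test` with elements `statistic`, `df`,
#'   `p_value`, `observed`, `expected` (per-group event counts) and `n`
#'   (group sizes).
#' @export
logrank <- function(times, events, group) {
  stopifnot(length(times) == length(events), length(times) == length(group))
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("need at least two groups")
  if (any(table(group) == 0)) stop("empty group")
  if (sum(events) < 1) stop("no events observed")

  g <- nlevels(group)
  tt <- sort(unique(times[events == 1]))
  O <- E <- stats::setNames(numeric(g), levels(group))
  V <- matrix(0, g, g)
  for (t in tt) {
    at_risk <- times >= t
    n_t <- sum(at_risk)
    d_t <- sum(events == 1 & times == t)
    n_gt <- vapply(levels(group), function(l) sum(at_risk & group == l),
                   numeric(1))
    d_gt <- vapply(levels(group),
                   function(l) sum(events == 1 & times == t & group == l),
                   numeric(1))
    O <- O + d_gt
    E <- E + d_t * n_gt / n_t
    if (n_t > 1) {
      frac <- n_gt / n_t
      v <- d_t * (n_t - d_t) / (n_t - 1) *
        (diag(frac, g) - tcrossprod(frac))
      V <- V + v
    }
  }
  idx <- seq_len(g - 1)
  u <- (O - E)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  stat <- if (all(abs(u) < 1e-12)) 0 else {
    as.numeric(crossprod(u, solve(Vi, u)))
  }
  structure(list(statistic = stat, df = g - 1,
                 p_value = stats::pchisq(stat, df = g - 1, lower.tail = FALSE),
                 observed = O, expected = E, n = table(group)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# encode the recognised clinical covariates as model terms; unknowns -> NA
.covariate_frame <- function(ct, covariates) {
  enc <- list(
    er = function(d) ifelse(d$er == "unknown", NA, as.numeric(d$er == "pos")),
    ln = function(d) ifelse(d$ln == "unknown", NA, as.numeric(d$ln == "pos")),
    grade3 = function(d) ifelse(d$grade == "unknown" | is.na(d$grade), NA,
                                as.numeric(d$grade == 3 | d$grade == "3")),
    age_gt50 = function(d) as.numeric(d$age_gt50),
    size_gt20mm = function(d) as.numeric(d$size_gt20mm)
  )
  bad <- setdiff(covariates, names(enc))
  if (length(bad)) stop("unknown covariates: ", paste(bad, collapse = ", "))
  out <- lapply(covariates, function(v) {
    col <- sub("3$|_gt50$|_gt20mm$", "", v)
    col <- c(grade = "grade", er = "er", ln = "ln", age = "age_gt50",
             size = "size_gt20mm")[[col]]
    if (!col %in% names(ct)) stop("clinical table lacks column: ", col)
    enc[[v]](ct)
  })
  names(out) <- covariates
  as.data.frame(out)
}

#' Multivariate Cox proportional-hazards evaluation of a stratification
#'
#' Fits a proportional-hazards model with the stratification group as a
#' binary covariate (risk level = `positive`/`high`) optionally adjusted
#' for the standard clinical covariates; the Efron approximation handles
#' tied event times.  Patients with unknown values for a requested
#' covariate are excluded listwise (with a message); the log-rank test on
#' the group labels is reported alongside.
#'
#' @param ct a [clinical_table()].
#' @param groups a `stratification` data.frame (`sample_id`, `group`) or a
#'   named vector of group labels.
#' @param covariates subset of
#'   `c("er", "ln", "grade3", "age_gt50", "size_gt20mm")`.
#' @return a list of class `survival_summary` with `cox` (data.frame:
#'   `term`, `hr`, `ci_low`, `ci_high`, `p` — Wald), `logrank` (on the
#'   full, unexcluded cohort), `n_used`, `n_excluded`, `group_sizes`.
#' @export
cox_fit <- function(ct, groups, covariates = character()) {
  if (inherits(groups, "stratification") || is.data.frame(groups))
    groups <- stats::setNames(groups$group, groups$sample_id)
  lab <- as.character(groups[match(ct$sample_id, names(groups))])
  if (anyNA(lab)) stop("group labels missing for some patients")
  risk <- as.numeric(lab %in% c("positive", "high"))
  if (length(unique(risk)) < 2) stop("stratification has a single group")

  lr <- logrank(ct$time, ct$event, lab)

  dat <- data.frame(time = ct$time, event = ct$event, group = risk)
  if (length(covariates))
    dat <- cbind(dat, .covariate_frame(ct, covariates))
  keep <- stats::complete.cases(dat)
  n_excl <- sum(!keep)
  if (n_excl > 0)
    message(n_excl, " patient(s) excluded for unknown covariate values")
  dat <- dat[keep, , drop = FALSE]

  for (v in c("group", covariates))
    if (length(unique(dat[[v]])) < 2)
      stop("covariate with a single level after filtering: ", v)

  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(c("group", covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w)))
        stop("Cox model failed to converge (possible perfect separation): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit)))
    stop("collinear covariates in Cox model: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))

  s <- summary(fit)
  cox <- data.frame(term = rownames(s$coefficients),
                    hr = s$conf.int[, "exp(coef)"],
                    ci_low = s$conf.int[, "lower .95"],
                    ci_high = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(cox = cox, logrank = lr, n_used = nrow(dat),
                 n_excluded = n_excl, group_sizes = table(lab)),
            class = "survival_summary")
}

#' @export
print.survival_summary <- function(x, ...) {
  cat(sprintf("log-rank p = %.4g; Cox fit on %d patients (%d excluded)\n",
              x$logrank$p_value, x$n_used, x$n_excluded))
  df <- x$cox
  df$hr <- sprintf("%.2f (%.2f-%.2f)", df$hr, df$ci_low, df$ci_high)
  print(df[, c("term", "hr", "p")], row.names = FALSE)
  invisible(x)
}
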