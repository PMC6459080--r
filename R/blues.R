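#' Genotype BLUEs across trials
#'
#' Fits the across-trial model with fixed genotype effects and random trial,
#' replicate-in-trial and sub-block-in-replicate-in-trial effects at their
#' REML variances, returning one generalized-least-squares estimate per
#' entry.  When every random variance is zero the GLS degenerates to
#' ordinary least squares (entry means in balanced data).
#'
#' @param scores data.frame with columns `entry_id`, `trial`, `rep`,
#'   `subblock` and the trait.
#' @param trait Trait column name.
#' @param entries Optional character vector of entries to report; entries
#'   absent from the data get `NA` (not zero).
#' @return Named numeric vector of BLUEs.
#' @export
compute_blues <- function(scores, trait, entries = NULL) {
  dat <- data.frame(
    y = scores[[trait]],
    g = factor(scores$entry_id),
    trial = factor(scores$trial),
    rep_in_trial = interaction(scores$trial, scores$rep, drop = TRUE),
    sub_in_rep = interaction(scores$trial, scores$rep, scores$subblock,
                             drop = TRUE)
  )
  dat <- dat[is.finite(dat$y), ]
  dat$g <- droplevels(dat$g)
  single_trial <- nlevels(dat$trial) < 2L
  form <- if (single_trial) {
    y ~ 0 + g + (1 | rep_in_trial) + (1 | sub_in_rep)
  } else {
    y ~ 0 + g + (1 | trial) + (1 | rep_in_trial) + (1 | sub_in_rep)
  }
  fit <- suppressMessages(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)))
  fe <- lme4::fixef(fit)
  names(fe) <- sub("^g", "", names(fe))
  if (is.null(entries)) entries <- levels(dat$g)
  out <- stats::setNames(rep(NA_real_, length(entries)), entries)
  found <- intersect(entries, names(fe))
  out[found] <- fe[found]
  out
}

#' Two-step adjusted means across years
#'
#' Fixed-effects least squares with genotype and year as fixed terms;
#' returns genotype means adjusted to the average year, so a constant added
#' to one year's observations leaves genotype contrasts unchanged.  With a
#' single year this reduces to entry means.
#'
#' @param y Numeric response (typically within-year BLUEs stacked over
#'   years).
#' @param genotype Factor of genotype identities.
#' @param year Factor of year identities.
#' @return Named numeric vector of adjusted means per genotype.
#' @export
adjusted_means_two_step <- function(y, genotype, year) {
  genotype <- droplevels(as.factor(genotype))
  year <- droplevels(as.factor(year))
  ok <- is.finite(y)
  dat <- data.frame(y = y[ok], g = genotype[ok], e = year[ok])
  dat$g <- droplevels(dat$g)
  dat$e <- droplevels(dat$e)
  if (nlevels(dat$e) < 2L) {
    return(tapply(dat$y, dat$g, mean))
  }
  fit <- stats::lm(y ~ 0 + g + e, data = dat)
  cf <- stats::coef(fit)
  gcf <- cf[grep("^g", names(cf))]
  names(gcf) <- sub("^g", "", names(gcf))
  ecf <- cf[grep("^e", names(cf))]
  # year effects relative to the first level; adjust to the average year
  year_adj <- mean(c(0, unname(ecf)), na.rm = TRUE)
  gcf + year_adj
}
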