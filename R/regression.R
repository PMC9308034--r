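# Linking regional resilience to physician-level scores: per specialty an
# ordinary least squares fit L ~ r * risk + b * benefit + const across
# federal states, with cross-specialty averages of the coefficients.

#' Regress critical limits on state-level risk and benefit scores
#'
#' For each specialty `j` fits `L_j ~ r_j * risk_j + b_j * benefit_j + const`
#' by OLS across federal states, where `L_j` is the critical limit (`L_FC` or
#' `L_LP`, both fitted) per state and `risk_j` / `benefit_j` are the
#' state-mean scores. Cross-specialty means and standard deviations of the
#' coefficients summarise how strongly the scores predict resilience.
#'
#' @param limits Tibble with `specialty`, `region`, `L_FC`, `L_LP` (e.g.
#'   [critical_limits()] computed per specialty and bound together).
#' @param scores Tibble with `specialty`, `region`, `risk`, `benefit` (see
#'   [state_score_means()]).
#' @param min_states Minimum number of complete states required per
#'   specialty (default 4); specialties below it are flagged and skipped.
#' @return A `care_regression` object; see [tidy()] and [glance()] methods.
#' @export
score_resilience_regression <- function(limits, scores, min_states = 4) {
  dat <- dplyr::inner_join(tibble::as_tibble(limits),
                           tibble::as_tibble(scores),
                           by = c("specialty", "region"))
  fits <- list()
  coef_rows <- list()
  for (sp in unique(dat$specialty)) {
    d <- dat[dat$specialty == sp, ]
    for (outcome in c("L_FC", "L_LP")) {
      dd <- d[, c(outcome, "risk", "benefit")]
      names(dd)[1] <- "L"
      dd <- dd[complete.cases(dd), ]
      key <- paste(sp, outcome, sep = ".")
      if (nrow(dd) < min_states) {
        coef_rows[[key]] <- tibble::tibble(
          specialty = sp, outcome = outcome,
          term = c("(Intercept)", "risk", "benefit"),
          estimate = NA_real_, flag = "insufficient_states")
        next
      }
      rank_ok <- qr(cbind(1, dd$risk, dd$benefit))$rank == 3
      if (!rank_ok) {
        coef_rows[[key]] <- tibble::tibble(
          specialty = sp, outcome = outcome,
          term = c("(Intercept)", "risk", "benefit"),
          estimate = NA_real_, flag = "rank_deficient")
        next
      }
      fit <- lm(L ~ risk + benefit, data = dd)
      fits[[key]] <- fit
      coef_rows[[key]] <- tibble::tibble(
        specialty = sp, outcome = outcome,
        term = names(coef(fit)), estimate = unname(coef(fit)),
        flag = NA_character_)
    }
  }
  coefs <- dplyr::bind_rows(coef_rows)
  summary_tbl <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(coefs, .data$term != "(Intercept)"),
                    .data$outcome, .data$term),
    mean = mean(.data$estimate, na.rm = TRUE),
    sd = sd_or_zero(.data$estimate[!is.na(.data$estimate)]),
    n_specialties = sum(!is.na(.data$estimate)),
    .groups = "drop"
  )
  structure(list(coefficients = coefs, summary = summary_tbl, fits = fits,
                 data = dat),
            class = "care_regression")
}

#' @export
print.care_regression <- function(x, ...) {
  cat("<care_regression> critical limits ~ risk + benefit, per specialty\n")
  print(x$summary)
  invisible(x)
}

#' Tidy the per-specialty regression coefficients
#'
#' @param x A `care_regression`.
#' @param ... Unused.
#' @return Tibble with `specialty`, `outcome`, `term`, `estimate`, `flag`.
#' @export
tidy.care_regression <- function(x, ...) x$coefficients

#' One-row-per-fit summary of the score-resilience regressions
#'
#' @param x A `care_regression`.
#' @param ... Unused.
#' @return Tibble with `specialty`, `outcome`, `r.squared`, `sigma`, `nobs`.
#' @export
glance.care_regression <- function(x, ...) {
  if (length(x$fits) == 0) {
    return(tibble::tibble(specialty = character(), outcome = character(),
                          r.squared = numeric(), sigma = numeric(),
                          nobs = integer()))
  }
  purrr::map_dfr(names(x$fits), function(key) {
    fit <- x$fits[[key]]
    sm <- summary(fit)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    tibble::tibble(specialty = parts[1], outcome = parts[2],
                   r.squared = sm$r.squared, sigma = sm$sigma,
                   nobs = length(fit$residuals))
  })
}
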