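#' Score recognition-test behaviour
#'
#' Classifies each test trial: intact + "old" response is a hit, intact +
#' "new" a miss, recombined + "new" a correct rejection (CR), recombined +
#' "old" a false alarm (FA); absent responses are "no response". Corrected
#' recognition is p(hit) - p(FA). By default proportions use all presented
#' trials of that status as the denominator (so no-responses count against
#' accuracy); \code{denominator = "responded"} excludes them.
#'
#' @param events test-phase \code{event_table} rows for one subject with
#'   \code{status} (intact/recombined) and \code{response}
#'   (old/new/none or NA).
#' @param denominator \code{"presented"} (default) or \code{"responded"}.
#' @return list of class \code{behavioral_summary}: counts (\code{hits},
#'   \code{crs}, \code{fas}, \code{misses}, \code{no_response}),
#'   proportions (\code{p_hit}, \code{p_fa}, \code{p_cr}, \code{p_miss})
#'   and \code{corrected_recognition}.
#' @export
score_behavior <- function(events, denominator = c("presented", "responded")) {
  denominator <- match.arg(denominator)
  ev <- events[events$phase == "test", , drop = FALSE]
  stopifnot(nrow(ev) > 0, all(ev$status %in% c("intact", "recombined")))
  resp <- ev$response
  resp[is.na(resp)] <- "none"
  bad <- setdiff(unique(resp), c("old", "new", "none"))
  if (length(bad)) stop("unknown response code(s): ", paste(bad, collapse = ", "))
  intact <- ev$status == "intact"
  hits <- sum(intact & resp == "old")
  misses <- sum(intact & resp == "new")
  crs <- sum(!intact & resp == "new")
  fas <- sum(!intact & resp == "old")
  nr_int <- sum(intact & resp == "none")
  nr_rec <- sum(!intact & resp == "none")
  den_int <- if (denominator == "presented") sum(intact) else sum(intact) - nr_int
  den_rec <- if (denominator == "presented") sum(!intact) else sum(!intact) - nr_rec
  out <- list(hits = hits, crs = crs, fas = fas, misses = misses,
              no_response = nr_int + nr_rec,
              n_intact = sum(intact), n_recombined = sum(!intact),
              p_hit = hits / den_int, p_miss = misses / den_int,
              p_cr = crs / den_rec, p_fa = fas / den_rec)
  out$corrected_recognition <- out$p_hit - out$p_fa
  class(out) <- "behavioral_summary"
  out
}

#' Outcome labels for test trials
#'
#' Vectorised trial-level outcome coding used to fill the \code{outcome}
#' column of an event table.
#'
#' @param status intact/recombined.
#' @param response old/new/none (NA treated as none).
#' @return character vector: hit, miss, CR, FA or none.
#' @export
classify_outcome <- function(status, response) {
  response[is.na(response)] <- "none"
  out <- rep("none", length(status))
  out[status == "intact" & response == "old"] <- "hit"
  out[status == "intact" & response == "new"] <- "miss"
  out[status == "recombined" & response == "new"] <- "CR"
  out[status == "recombined" & response == "old"] <- "FA"
  out
}

#' Independent-samples t test from summary statistics or raw data
#'
#' Pooled-variance (Student) t by default, matching df = n1 + n2 - 2;
#' Welch's unequal-variance form is available. Cohen's d uses the pooled
#' standard deviation.
#'
#' @param mean1 group-1 mean, or a numeric vector of group-1 values (then
#'   \code{sd1} must be the group-2 vector and the remaining summary
#'   arguments are ignored).
#' @param sd1,n1,mean2,sd2,n2 summary statistics.
#' @param var_equal pooled variance if TRUE (default).
#' @return list: \code{t}, \code{df}, \code{p} (two-sided),
#'   \code{cohen_d}, \code{mean_diff}.
#' @export
independent_t <- function(mean1, sd1 = NULL, n1 = NULL, mean2 = NULL,
                          sd2 = NULL, n2 = NULL, var_equal = TRUE) {
  if (length(mean1) > 1L) {
    x <- mean1; y <- sd1
    mean1 <- mean(x); sd1 <- sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- sd(y); n2 <- length(y)
  }
  stopifnot(n1 >= 2, n2 >= 2)
  if (sd1 == 0 && sd2 == 0) stop("zero variance in both groups")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (var_equal) {
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- se^4 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  tval <- (mean1 - mean2) / se
  list(t = tval, df = df, p = 2 * pt(abs(tval), df, lower.tail = FALSE),
       cohen_d = (mean1 - mean2) / sqrt(sp2), mean_diff = mean1 - mean2)
}

#' Paired-samples t test
#'
#' @param a,b numeric vectors of equal length (condition values per
#'   subject); the test is on \code{a - b}.
#' @return list: \code{t}, \code{df}, \code{p} (two-sided),
#'   \code{mean_diff}, \code{cohen_dz}.
#' @export
paired_t <- function(a, b = 0) {
  d <- a - b
  d <- d[!is.na(d)]
  n <- length(d)
  stopifnot(n >= 2)
  s <- sd(d)
  if (s == 0) {
    tval <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
  } else {
    tval <- mean(d) / (s / sqrt(n))
  }
  list(t = tval, df = n - 1,
       p = 2 * pt(abs(tval), n - 1, lower.tail = FALSE),
       mean_diff = mean(d), cohen_dz = if (s == 0) NA_real_ else mean(d) / s)
}

#' Mixed (split-plot) ANOVA: one between factor, one within factor
#'
#' Classical balanced-design partition: the between-subject effect (Group)
#' is tested against subjects-within-groups, the within effect (Level) and
#' the Group x Level interaction against the Level x subjects-within-groups
#' residual. Requires every subject to have exactly one value at every
#' level.
#'
#' @param data data.frame with columns \code{subject}, \code{group},
#'   \code{level}, \code{value} (long format).
#' @return data.frame of class \code{anova_table} with one row per effect
#'   (group, level, group:level) and the two error strata: columns
#'   \code{effect}, \code{ss}, \code{df}, \code{ms}, \code{F}, \code{p}.
#' @export
mixed_anova <- function(data) {
  need <- c("subject", "group", "level", "value")
  stopifnot(all(need %in% names(data)))
  data$subject <- as.character(data$subject)
  data$group <- as.character(data$group)
  data$level <- as.character(data$level)
  tab <- table(data$subject, data$level)
  if (any(tab != 1L)) stop("missing cells: each subject needs one value per level")
  subj_group <- unique(data[, c("subject", "group")])
  if (anyDuplicated(subj_group$subject)) stop("subject assigned to two groups")

  N <- nrow(subj_group)                 # subjects
  L <- length(unique(data$level))       # within levels
  G <- length(unique(data$group))
  grand <- mean(data$value)
  ss_total <- sum((data$value - grand)^2)

  subj_means <- tapply(data$value, data$subject, mean)
  ss_between_subj <- L * sum((subj_means - grand)^2)

  grp_means <- tapply(data$value, data$group, mean)
  n_per_grp <- table(subj_group$group)[names(grp_means)]
  ss_group <- L * sum(n_per_grp * (grp_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group

  lev_means <- tapply(data$value, data$level, mean)
  ss_level <- N * sum((lev_means - grand)^2)

  cell_means <- tapply(data$value, list(data$group, data$level), mean)
  gl <- expand.grid(group = rownames(cell_means), level = colnames(cell_means),
                    stringsAsFactors = FALSE)
  dev <- cell_means[cbind(gl$group, gl$level)] -
    grp_means[gl$group] - lev_means[gl$level] + grand
  ss_inter <- sum(as.numeric(n_per_grp[gl$group]) * dev^2)

  ss_within <- ss_total - ss_between_subj
  ss_err <- ss_within - ss_level - ss_inter

  df <- c(group = G - 1, subj_within = N - G,
          level = L - 1, inter = (G - 1) * (L - 1),
          err = (N - G) * (L - 1))
  ss <- c(ss_group, ss_subj_within, ss_level, ss_inter, ss_err)
  ms <- ss / df
  if ((ms[2] <= 0 && ss[1] > 0) || (ms[5] <= 0 && (ss[3] > 0 || ss[4] > 0)))
    stop("degenerate error variance")
  # effects with zero sum of squares are exactly null (F = 0), even when
  # the error stratum is also zero (all-equal data)
  # with a single group the Group and Group x Level strata are empty
  Fv <- c(if (G == 1) NA_real_ else if (ss[1] == 0) 0 else ms[1] / ms[2], NA,
          if (ss[3] == 0) 0 else ms[3] / ms[5],
          if (G == 1) NA_real_ else if (ss[4] == 0) 0 else ms[4] / ms[5], NA)
  pv <- c(if (G == 1) NA_real_ else
            pf(Fv[1], df[1], df[2], lower.tail = FALSE), NA,
          pf(Fv[3], df[3], df[5], lower.tail = FALSE),
          if (G == 1) NA_real_ else
            pf(Fv[4], df[4], df[5], lower.tail = FALSE), NA)
  out <- data.frame(
    effect = c("group", "subjects_within_groups", "level", "group:level",
               "level_x_subjects_error"),
    ss = ss, df = as.numeric(df), ms = ms, F = Fv, p = pv,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Bonferroni-adjusted alpha
#'
#' @param alpha family-wise error level.
#' @param m number of tests (>= 1).
#' @return \code{alpha / m} (e.g. 0.05/4 = 0.0125; 0.05/3 = 0.0167).
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(m >= 1)
  alpha / m
}
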