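# Cohort statistics layer: compartment densities, median/mean/quartile
# dichotomization, five-year Cox proportional-hazards models with FDR
# control, Pearson correlation matrices, ANOVA, Kaplan-Meier summaries.

#' Administrative censoring at an analysis horizon
#'
#' Times beyond the horizon are truncated to it and their events removed
#' ("five-year" outcomes = 60-month administrative censoring).
#'
#' @param time,event numeric time (months) and 0/1 event indicator.
#' @param horizon months (default 60).
#' @return list with \code{time}, \code{event}.
#' @export
adminCensor <- function(time, event, horizon = 60) {
  over <- time > horizon
  list(time = pmin(time, horizon), event = as.integer(event == 1 & !over))
}

.endpointCols <- function(endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  c(time = paste0(endpoint, "_months"), event = paste0(endpoint, "_event"))
}

#' Per-patient phenotype densities by compartment
#'
#' Cells of each phenotype per mm^2 of compartment area in each core,
#' averaged over the patient's valid cores. Zero cells is density 0, not
#' missing; a core/compartment with area <= 0 but cells present is
#' skipped with a message.
#'
#' @param cellTable phenotyped cell table.
#' @param areas per-core areas (\code{core_id}, \code{patient_id},
#'   \code{area_epithelium_mm2}, \code{area_stroma_mm2}).
#' @param phenotypes phenotype levels to tabulate (default: observed).
#' @return data.frame: patient_id, phenotype, compartment, density.
#' @export
cellDensities <- function(cellTable, areas, phenotypes = NULL) {
  if (is.null(phenotypes)) phenotypes <- sort(unique(cellTable$phenotype))
  skipped <- 0L
  rows <- list()
  for (comp in COMPARTMENTS) {
    acol <- paste0("area_", comp, "_mm2")
    sub <- cellTable[cellTable$compartment == comp, ]
    cnt <- table(factor(sub$core_id, levels = areas$core_id),
                 factor(sub$phenotype, levels = phenotypes))
    a <- areas[[acol]]
    ok <- a > 0
    bad <- !ok & rowSums(cnt) > 0
    skipped <- skipped + sum(bad)
    dens <- sweep(as.matrix(cnt), 1L, ifelse(ok, a, NA), "/")
    for (p in phenotypes) {
      d <- data.frame(patient_id = areas$patient_id, core_id = areas$core_id,
                      phenotype = p, compartment = comp,
                      density = dens[, p], stringsAsFactors = FALSE)
      rows[[paste(comp, p)]] <- d
    }
  }
  if (skipped > 0L)
    message(skipped, " core/compartment(s) with cells but area <= 0 skipped")
  long <- do.call(rbind, rows)
  out <- aggregate(density ~ patient_id + phenotype + compartment,
                   data = long, FUN = mean, na.rm = TRUE, na.action = NULL)
  out$density[is.nan(out$density)] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Dichotomize a per-patient variable
#'
#' Median mode: "high" is strictly above the cohort median (ties low);
#' mean mode analogous; quartile mode assigns only the lowest (Q1) and
#' highest (Q4) quartiles, the middle half is missing.
#'
#' @param values numeric vector (typically named by patient).
#' @param mode "median", "mean" or "quartile".
#' @return factor of the same length (levels low/high or Q1/Q4, NA in the
#'   quartile middle), with attributes \code{split} (the cut value(s)) and
#'   \code{degenerate} (TRUE when all values are identical: no split).
#' @export
dichotomize <- function(values, mode = c("median", "mean", "quartile")) {
  mode <- match.arg(mode)
  v <- values
  ok <- !is.na(v)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  if (length(unique(v[ok])) == 1L) {
    out <- factor(rep(NA_character_, length(v)), levels = c("low", "high"))
    attr(out, "split") <- unique(v[ok])
    attr(out, "degenerate") <- TRUE
    warning("all values identical: degenerate split")
    return(out)
  }
  if (mode %in% c("median", "mean")) {
    cut <- if (mode == "median") median(v[ok]) else mean(v[ok])
    g <- ifelse(v > cut, "high", "low")
    out <- factor(g, levels = c("low", "high"))
    attr(out, "split") <- cut
  } else {
    q <- quantile(v[ok], c(0.25, 0.75), names = FALSE)
    g <- rep(NA_character_, length(v))
    g[ok & v <= q[1]] <- "Q1"
    g[ok & v > q[2]] <- "Q4"
    out <- factor(g, levels = c("Q1", "Q4"))
    attr(out, "split") <- q
  }
  attr(out, "degenerate") <- FALSE
  out
}

.coxRow <- function(fit, varname, endpoint, n, nev, type, flagged = FALSE) {
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  out <- data.frame(
    variable = if (nrow(co) == 1L) varname else rownames(co),
    endpoint = toupper(endpoint),
    hr = unname(co[, "exp(coef)"]),
    ci_low = unname(ci[, "lower .95"]),
    ci_high = unname(ci[, "upper .95"]),
    p = unname(co[, "Pr(>|z|)"]),
    p_adj = NA_real_,
    n = n, n_events = nev, model = type,
    flagged = flagged, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Univariate Cox proportional-hazards model at a five-year horizon
#'
#' Administrative censoring at \code{horizon} months, then a Cox partial
#' likelihood with Breslow tie handling; HR = exp(beta) with Wald 95% CI
#' and p. Factor/character variables are coded against their first level;
#' numeric variables enter continuously.
#'
#' @param data patient-level data.frame carrying the variable and the
#'   endpoint columns (\code{os_months}/\code{os_event} or pfs).
#' @param variable column name.
#' @param endpoint "os" or "pfs".
#' @param horizon months (default 60).
#' @return one-row \code{SurvivalResult} data.frame (variable, endpoint,
#'   hr, ci_low, ci_high, p, p_adj, n, n_events, model, flagged), or NULL
#'   with a warning when no events remain after truncation. Monotone
#'   likelihood (separation) sets \code{flagged}.
#' @export
coxUnivariate <- function(data, variable, endpoint = c("os", "pfs"),
                          horizon = 60) {
  endpoint <- match.arg(endpoint)
  cols <- .endpointCols(endpoint)
  miss <- setdiff(c(cols, variable), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  v <- data[[variable]]
  ac <- adminCensor(data[[cols["time"]]], data[[cols["event"]]], horizon)
  keep <- !is.na(v) & !is.na(ac$time)
  if (is.character(v)) v <- factor(v)
  df <- data.frame(time = ac$time[keep], event = ac$event[keep], x = v[keep])
  if (sum(df$event) < 1L) {
    warning("no events after truncation for ", variable, " (", endpoint, ")")
    return(NULL)
  }
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, data = df,
                    ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w)))
        flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  .coxRow(fit, variable, endpoint, nrow(df), sum(df$event), "univariate",
          flagged)
}

#' Multivariate Cox model over univariately significant variables
#'
#' Runs the univariate pass over all candidate variables, BH-adjusts its
#' p-values, and fits one joint Cox model containing the variables with
#' adjusted p below the selection threshold (set \code{select = FALSE} to
#' fit all candidates jointly). Collinear variables are dropped with a
#' warning.
#'
#' @param data patient-level data.frame.
#' @param variables candidate column names.
#' @param endpoint "os" or "pfs".
#' @param horizon months.
#' @param select apply the univariate adjusted p < \code{alpha} filter.
#' @param alpha selection threshold (default 0.05).
#' @return list: \code{univariate} (all candidates, p_adj filled),
#'   \code{multivariate} (per-variable rows of the joint model, or NULL if
#'   nothing was selected), \code{selected} (character).
#' @export
coxMultivariate <- function(data, variables, endpoint = c("os", "pfs"),
                            horizon = 60, select = TRUE, alpha = 0.05) {
  endpoint <- match.arg(endpoint)
  uni <- do.call(rbind, lapply(variables, function(v)
    coxUnivariate(data, v, endpoint, horizon)))
  # adjust across the candidate family; map back by variable name prefix
  uniVar <- vapply(variables, function(v) {
    r <- uni[startsWith(uni$variable, v) | uni$variable == v, , drop = FALSE]
    if (nrow(r)) min(r$p) else NA_real_
  }, numeric(1))
  adj <- fdrAdjust(uniVar[!is.na(uniVar)])
  uniVarAdj <- setNames(rep(NA_real_, length(variables)), variables)
  uniVarAdj[names(adj)] <- adj
  for (v in variables)
    uni$p_adj[startsWith(uni$variable, v)] <- uniVarAdj[[v]]
  selected <- if (select) variables[!is.na(uniVarAdj) & uniVarAdj < alpha]
              else variables
  if (!length(selected)) {
    message("no variable passes univariate selection at adjusted p < ", alpha)
    return(list(univariate = uni, multivariate = NULL,
                selected = character(0)))
  }
  cols <- .endpointCols(endpoint)
  ac <- adminCensor(data[[cols["time"]]], data[[cols["event"]]], horizon)
  df <- data.frame(time = ac$time, event = ac$event)
  for (v in selected)
    df[[v]] <- if (is.character(data[[v]])) factor(data[[v]]) else data[[v]]
  df <- df[stats::complete.cases(df), ]
  form <- as.formula(paste("survival::Surv(time, event) ~",
                           paste(selected, collapse = " + ")))
  fit <- suppressWarnings(survival::coxph(form, data = df, ties = "breslow"))
  if (any(is.na(stats::coef(fit)))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    warning("collinear variable(s) dropped: ", paste(dropped, collapse = ", "))
    keepv <- selected[vapply(selected, function(v)
      !all(startsWith(dropped, v)), logical(1))]
    form <- as.formula(paste("survival::Surv(time, event) ~",
                             paste(keepv, collapse = " + ")))
    fit <- suppressWarnings(survival::coxph(form, data = df, ties = "breslow"))
  }
  multi <- .coxRow(fit, paste(selected, collapse = "+"), endpoint,
                   nrow(df), sum(df$event), "multivariate")
  list(univariate = uni, multivariate = multi, selected = selected)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' The "fdr" method of \code{stats::p.adjust} (step-up, monotone, capped
#' at 1), with input validation.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values, names preserved.
#' @export
fdrAdjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "fdr")
}

#' Pairwise Pearson correlation matrix
#'
#' Pairwise-complete Pearson r over the numeric columns; cells with fewer
#' than \code{minPairs} complete pairs and zero-variance variables are
#' NA.
#'
#' @param data data.frame or matrix (patients x variables).
#' @param minPairs minimum complete pairs per cell (default 3).
#' @return symmetric correlation matrix with unit diagonal where defined.
#' @export
pearsonMatrix <- function(data, minPairs = 3L) {
  X <- as.matrix(data)
  if (!is.numeric(X)) stop("all variables must be numeric")
  r <- suppressWarnings(cor(X, use = "pairwise.complete.obs",
                            method = "pearson"))
  npair <- crossprod(!is.na(X))
  r[npair < minPairs] <- NA_real_
  zv <- apply(X, 2L, function(col) {
    col <- col[!is.na(col)]
    length(col) < 2L || var(col) == 0
  })
  r[zv, ] <- NA_real_
  r[, zv] <- NA_real_
  r
}

#' One- or two-way ANOVA with BH-FDR across the tested family
#'
#' One response and one factor gives a one-way ANOVA; two factors give a
#' two-way ANOVA with type-II sums of squares (main effects and
#' interaction). Multiple responses may be tested in one call; adjusted
#' p-values are BH across every effect tested in the call.
#'
#' @param data data.frame.
#' @param responses response column name(s).
#' @param factors one or two factor column names.
#' @return data.frame: response, effect, F, p, p_adj.
#' @export
anovaFdr <- function(data, responses, factors) {
  if (!length(factors) %in% 1:2) stop("one or two factors required")
  rows <- list()
  for (resp in responses) {
    df <- data[c(resp, factors)]
    df <- df[stats::complete.cases(df), ]
    for (f in factors) df[[f]] <- factor(df[[f]])
    grpSizes <- table(interaction(df[factors]))
    if (length(factors) == 1L) {
      if (nlevels(df[[factors]]) < 2L || any(table(df[[factors]]) < 2L)) {
        message("ANOVA for ", resp, ": group with < 2 observations; skipped")
        next
      }
      fit <- aov(as.formula(paste(resp, "~", factors)), data = df)
      s <- summary(fit)[[1L]]
      rows[[paste(resp, factors)]] <- data.frame(
        response = resp, effect = factors,
        F = s$`F value`[1L], p = s$`Pr(>F)`[1L], stringsAsFactors = FALSE)
    } else {
      fit <- stats::lm(as.formula(paste(resp, "~", factors[1L], "*",
                                        factors[2L])), data = df)
      a <- car::Anova(fit, type = 2)
      eff <- rownames(a)
      keep <- eff != "Residuals"
      rows[[paste(resp, "2way")]] <- data.frame(
        response = resp, effect = eff[keep],
        F = a$`F value`[keep], p = a$`Pr(>F)`[keep],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable contrasts")
  out$p_adj <- fdrAdjust(out$p)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier step function per group
#'
#' Product-limit estimator after administrative censoring at the horizon;
#' the returned table doubles as a risk table.
#'
#' @param data patient-level data.frame.
#' @param group grouping column name (or NULL for one curve).
#' @param endpoint "os" or "pfs".
#' @param horizon months.
#' @return data.frame: group, time, n_risk, n_event, n_censor, surv,
#'   lower, upper.
#' @export
kmCurve <- function(data, group = NULL, endpoint = c("os", "pfs"),
                    horizon = 60) {
  endpoint <- match.arg(endpoint)
  cols <- .endpointCols(endpoint)
  ac <- adminCensor(data[[cols["time"]]], data[[cols["event"]]], horizon)
  df <- data.frame(time = ac$time, event = ac$event)
  df$group <- if (is.null(group)) "all" else as.character(data[[group]])
  df <- df[!is.na(df$group) & !is.na(df$time), ]
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep("all", length(s$time))
         else sub("^group=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, n_censor = s$n.censor, surv = s$surv,
             lower = s$lower, upper = s$upper, stringsAsFactors = FALSE)
}
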