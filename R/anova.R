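#' Assemble a trial table of pairwise-comparison outcomes
#'
#' A trial table records one pairwise-comparison run per row: the factor
#' levels of the trial (whether artefactual surfaces were removed, the
#' comparison method, whether ICP fine alignment ran, and which reference
#' specimen was used) together with the outcome statistics (mean distance,
#' SD of distances, and the number of distance values).
#'
#' @param removal factor or character: `"yes"`/`"no"`.
#' @param method factor or character: `"C2M"`/`"C2C"`.
#' @param icp factor or character: `"yes"`/`"no"`.
#' @param reference factor or character reference-specimen id.
#' @param mean_distance,sd_distance numeric outcome statistics.
#' @param n_points integer count of distance values per trial.
#' @return A `data.frame` of class `"trial_table"`.
#' @export
trial_table <- function(removal, method, icp, reference, mean_distance,
                        sd_distance = NA_real_, n_points = NA_integer_) {
  tab <- data.frame(
    removal = factor(removal), method = factor(method), icp = factor(icp),
    reference = factor(reference),
    mean_distance = as.numeric(mean_distance),
    sd_distance = as.numeric(sd_distance),
    n_points = as.integer(n_points)
  )
  if (nrow(tab) < 2L) stop("a trial table needs at least 2 rows",
                           call. = FALSE)
  if (!all(is.finite(tab$mean_distance))) {
    stop("mean_distance must be finite", call. = FALSE)
  }
  combo <- interaction(tab$removal, tab$method, tab$icp, tab$reference,
                       drop = TRUE)
  if (anyDuplicated(combo)) {
    warning("duplicate factor combinations present in trial table",
            call. = FALSE)
  }
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Build a trial table from a list of comparison records
#'
#' Each record is a list with factor labels `removal`, `method`, `icp`,
#' `reference` and either a `summary` (a `field_summary`, e.g. from
#' [pairwise_compare()]) or explicit `mean_distance` / `sd_distance` /
#' `n_points` entries.
#'
#' @param records list of records as described.
#' @return A [trial_table()].
#' @export
build_trial_table <- function(records) {
  if (length(records) < 2L) {
    stop("a trial table needs at least 2 records", call. = FALSE)
  }
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    for (key in c("removal", "method", "icp", "reference")) {
      if (is.null(r[[key]])) {
        stop(sprintf("record %d: missing factor value '%s'", i, key),
             call. = FALSE)
      }
    }
    if (!is.null(r$summary)) {
      s <- r$summary
      data.frame(removal = r$removal, method = r$method, icp = r$icp,
                 reference = r$reference, mean_distance = s$mean,
                 sd_distance = s$sd, n_points = s$n)
    } else {
      data.frame(removal = r$removal, method = r$method, icp = r$icp,
                 reference = r$reference,
                 mean_distance = r$mean_distance,
                 sd_distance = r$sd_distance %||% NA_real_,
                 n_points = r$n_points %||% NA_integer_)
    }
  })
  df <- do.call(rbind, rows)
  trial_table(df$removal, df$method, df$icp, df$reference,
              df$mean_distance, df$sd_distance, df$n_points)
}

#' Read / write a trial table as CSV
#' @param path CSV file path with columns `removal`, `method`, `icp`,
#'   `reference`, `mean_distance`, and optionally `sd_distance`,
#'   `n_points`.
#' @return [read_trial_table()] returns a [trial_table()];
#'   [write_trial_table()] returns `path` invisibly.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("trial table not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("removal", "method", "icp", "reference", "mean_distance")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("trial table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  trial_table(df$removal, df$method, df$icp, df$reference,
              df$mean_distance,
              if ("sd_distance" %in% names(df)) df$sd_distance else NA,
              if ("n_points" %in% names(df)) df$n_points else NA)
}

#' @rdname read_trial_table
#' @param tab a [trial_table()].
#' @export
write_trial_table <- function(tab, path) {
  stopifnot(inherits(tab, "trial_table"))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled ungual comparison trial outcomes
#'
#' The twelve pairwise-comparison trials of the megaraptorid ungual case
#' study shipped with the package: a fragmentary theropod manual ungual
#' (NMV P186153) compared against two *Australovenator wintonensis*
#' reference unguals (AODF604 MCII-3 and MCI-2) under every combination of
#' artefact-surface removal, comparison method (C2M/C2C), and ICP fine
#' alignment, with the resulting mean distance, SD, and distance-value
#' count per trial.
#'
#' @return A [trial_table()] with 12 rows.
#' @export
ungual_trials <- function() {
  path <- system.file("extdata", "ungual_trials.csv",
                      package = "pairwise3d", mustWork = TRUE)
  read_trial_table(path)
}

#' Permutation-based type-II analysis of variance of trial outcomes
#'
#' Fits a main-effects linear model of the response on the trial factors
#' and decomposes it with type-II sums of squares: each factor's SS is the
#' residual SS of the model without that factor minus the residual SS of
#' the full model (each main effect adjusted for all others; with no
#' interaction terms this coincides with type III). F statistics use the
#' residual mean square. Inference is by unrestricted permutation of the
#' response rows: `p = (count(F* >= F_obs) + 1) / (B + 1)`, so the
#' smallest attainable p is `1/(B + 1)`; the effect size
#' `Z = (log F_obs - mean(log F*)) / sd(log F*)` standardises the observed
#' statistic against its permutation distribution on the log scale.
#'
#' @param tab a [trial_table()] or data frame with the factor columns and
#'   the response.
#' @param response response column name (default `"mean_distance"`).
#' @param factors character vector of factor column names.
#' @param n_permutations number of response permutations `B` (default 999);
#'   0 skips inference (p and Z are `NA`).
#' @param seed integer seed for the permutation stream.
#' @return A data frame of class `"perm_anova"` with one row per factor
#'   plus `Residuals` and `Total`; columns `Df`, `SS`, `MS`, `R2`, `F`,
#'   `Z`, `p`. Attributes: `"seed"`, `"n_permutations"`.
#' @export
anova_type2 <- function(tab, response = "mean_distance",
                        factors = c("removal", "method", "icp", "reference"),
                        n_permutations = 999L, seed = 1L) {
  df <- as.data.frame(tab)
  miss <- setdiff(c(response, factors), names(df))
  if (length(miss)) {
    stop(sprintf("column(s) not in table: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  y <- as.numeric(df[[response]])
  if (!all(is.finite(y))) stop("response must be finite", call. = FALSE)
  n <- length(y)
  fd <- df[factors]
  fd[] <- lapply(fd, function(x) factor(x))
  for (f in factors) {
    if (nlevels(fd[[f]]) < 2L) {
      stop(sprintf("factor '%s' has fewer than 2 levels", f), call. = FALSE)
    }
  }

  X_full <- stats::model.matrix(stats::reformulate(factors), fd)
  qr_full <- qr(X_full)
  rank_full <- qr_full$rank
  df_res <- n - rank_full
  if (df_res < 1L) {
    stop("model has no residual degrees of freedom", call. = FALSE)
  }
  qr_drop <- list()
  term_df <- integer(length(factors))
  names(term_df) <- factors
  for (f in factors) {
    others <- setdiff(factors, f)
    Xr <- if (length(others)) {
      stats::model.matrix(stats::reformulate(others), fd)
    } else {
      matrix(1, n, 1L)
    }
    qr_drop[[f]] <- qr(Xr)
    term_df[f] <- rank_full - qr_drop[[f]]$rank
    if (term_df[f] < 1L) {
      stop(sprintf(
        "factor '%s' is aliased with the other factors (0 df after adjustment)",
        f), call. = FALSE)
    }
  }

  rss <- function(qrx, yy) sum(qr.resid(qrx, yy)^2)
  decomp <- function(yy) {
    rss_full <- rss(qr_full, yy)
    ss <- vapply(factors, function(f) rss(qr_drop[[f]], yy) - rss_full,
                 numeric(1L))
    list(ss = pmax(ss, 0), rss = rss_full)
  }

  obs <- decomp(y)
  ss_total <- sum((y - mean(y))^2)
  ms_res <- obs$rss / df_res
  constant_response <- ss_total < .Machine$double.eps * n
  f_obs <- if (constant_response) {
    rep(NA_real_, length(factors))
  } else {
    (obs$ss / term_df) / ms_res
  }

  p_val <- z_val <- rep(NA_real_, length(factors))
  if (n_permutations > 0L && !constant_response) {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(b) {
        yy <- y[sample.int(n)]
        d <- decomp(yy)
        (d$ss / term_df) / (d$rss / df_res)
      }, numeric(length(factors)))
    })
    f_perm <- matrix(f_perm, nrow = length(factors))
    for (i in seq_along(factors)) {
      p_val[i] <- (sum(f_perm[i, ] >= f_obs[i]) + 1) / (n_permutations + 1)
      lf <- log(pmax(f_perm[i, ], .Machine$double.xmin))
      z_val[i] <- (log(f_obs[i]) - mean(lf)) / stats::sd(lf)
    }
  }

  term_names <- c(factors, "Residuals", "Total")
  out <- data.frame(
    Df = c(term_df, df_res, n - 1L),
    SS = c(obs$ss, obs$rss, ss_total),
    MS = c(obs$ss / term_df, ms_res, NA_real_),
    R2 = c(obs$ss, obs$rss, ss_total) / ss_total,
    F = c(f_obs, NA_real_, NA_real_),
    Z = c(z_val, NA_real_, NA_real_),
    p = c(p_val, NA_real_, NA_real_),
    row.names = term_names
  )
  if (constant_response) {
    out$SS[] <- c(rep(0, length(factors)), 0, 0)
    out$MS[] <- NA_real_
    out$R2[] <- NA_real_
  }
  out$R2[term_names == "Total"] <- if (constant_response) NA_real_ else 1
  attr(out, "seed") <- seed
  attr(out, "n_permutations") <- n_permutations
  attr(out, "response") <- response
  class(out) <- c("perm_anova", "data.frame")
  out
}

#' @export
print.perm_anova <- function(x, digits = 6L, ...) {
  cat(sprintf(
    "Permutation ANOVA (type II SS, %d permutations, seed %s) on '%s'\n",
    attr(x, "n_permutations"), format(attr(x, "seed")),
    attr(x, "response")))
  y <- as.data.frame(x)
  y$SS <- round(y$SS, digits)
  y$MS <- round(y$MS, digits)
  y$R2 <- round(y$R2, digits)
  y$F <- round(y$F, 4L)
  y$Z <- round(y$Z, 4L)
  print(y)
  invisible(x)
}
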