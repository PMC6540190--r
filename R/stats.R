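# Factorial statistics for drought phenotyping.
#
# For each response: Cochran's C test for variance homogeneity across cells and
# Shapiro-Wilk on the residuals (both reported as warnings, never blocking),
# two-way fixed-effects ANOVA (treatment, genotype, interaction), and Tukey
# comparisons routed by the interaction -- a significant interaction means the
# genotype means must be compared within each treatment; otherwise treatments
# are compared within each genotype. Group letters use the insert-and-absorb
# compact letter display. Pearson correlations are reported with the standard
# interpretation bands (negligible / low / moderate / high / very high).

#' Cochran's C test for homogeneity of variances
#'
#' `C = max(s_i^2) / sum(s_i^2)` over the k groups; the p-value uses the
#' classical bound `p = min(1, k * P(F(nu, (k-1) nu) > (k-1) C / (1 - C)))`
#' with `nu` the average within-group degrees of freedom.
#'
#' @param values numeric response vector.
#' @param groups grouping factor (the design cells).
#' @return list with `statistic` (C), `p.value`, `k`, `df`.
#' @export
cochran_c_test <- function(values, groups) {
  groups <- as.factor(groups)
  s2 <- tapply(values, groups, stats::var)
  n <- tapply(values, groups, length)
  if (any(n < 2)) stopf("every group needs at least 2 observations")
  k <- length(s2)
  nu <- mean(n - 1)
  if (sum(s2) == 0) {
    # all groups constant: no evidence of heterogeneity
    return(list(statistic = NA_real_, p.value = 1, k = k, df = nu))
  }
  C <- max(s2) / sum(s2)
  Fobs <- (k - 1) * C / (1 - C)
  p <- min(1, k * stats::pf(Fobs, nu, (k - 1) * nu, lower.tail = FALSE))
  list(statistic = C, p.value = p, k = k, df = nu)
}

# Tukey pairwise p-values from cell means at the model error df:
# q = |mi - mj| / sqrt(MSE/2 * (1/ni + 1/nj)), referred to the studentized
# range with `nmeans` means. Returns a symmetric matrix of adjusted p-values.
tukey_pairwise_p <- function(means, ns, mse, df_error, nmeans = length(means)) {
  k <- length(means)
  p <- matrix(1, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[i] - means[j]) / se
    p[i, j] <- p[j, i] <- stats::ptukey(q, nmeans, df_error, lower.tail = FALSE)
  }
  p
}

#' Two-factor analysis with interaction-dependent comparison routing
#'
#' Fits `response ~ treatment * genotype` (fixed effects), reports assumption
#' checks (Cochran's C across design cells, Shapiro-Wilk on residuals) as
#' non-blocking warnings, and routes the Tukey comparisons: a significant
#' interaction at `alpha` means genotype means are compared within each
#' treatment; otherwise treatments are compared within each genotype.
#' Pairwise p-values use the studentized range at the two-way model's error
#' degrees of freedom, and each comparison family is summarized by a compact
#' letter display.
#'
#' @param records data.frame with columns `genotype`, `treatment` and the
#'   response; >= 2 replicates per cell, complete crossing.
#' @param response name of the response column.
#' @param alpha significance level (default 0.05).
#' @return object of class `"analysis_result"`: `response`, `homogeneity_p`,
#'   `normality_p`, `anova_table`, `routing` (one of
#'   `"compare_within_treatment"`, `"compare_between_treatments"`),
#'   `significant` (any factor or interaction at `alpha`), `tukey` and
#'   `letters` (one entry per comparison family), `alpha`.
#' @export
factorial_analysis <- function(records, response, alpha = 0.05) {
  if (!response %in% names(records)) stopf("response '%s' not in records", response)
  df <- data.frame(y = records[[response]],
                   treatment = factor(records$treatment),
                   genotype = factor(records$genotype))
  if (any(!is.finite(df$y))) stopf("response contains non-finite values")
  cells <- table(df$treatment, df$genotype)
  if (any(cells == 0)) stopf("empty design cell(s): %s",
                             paste(which(cells == 0, arr.ind = TRUE), collapse = " "))
  if (any(cells < 2)) stopf("every treatment x genotype cell needs >= 2 replicates")

  fit <- stats::aov(y ~ treatment * genotype, data = df)
  at <- summary(fit)[[1]]
  rn <- trimws(rownames(at))
  anova_table <- data.frame(term = rn, df = at$Df, sum_sq = at$`Sum Sq`,
                            mean_sq = at$`Mean Sq`, F = at$`F value`,
                            p = at$`Pr(>F)`)

  cell_id <- interaction(df$treatment, df$genotype)
  hom <- cochran_c_test(df$y, cell_id)
  norm_p <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                     error = function(e) NA_real_)  # degenerate (constant) residuals
  if (hom$p.value <= alpha) {
    warnf("heterogeneous cell variances for %s (Cochran C, p = %.3g); analysis proceeds",
          response, hom$p.value)
  }
  if (is.finite(norm_p) && norm_p <= alpha) {
    warnf("non-normal residuals for %s (Shapiro-Wilk, p = %.3g); analysis proceeds",
          response, norm_p)
  }

  p_int <- anova_table$p[anova_table$term == "treatment:genotype"]
  p_main <- anova_table$p[anova_table$term %in% c("treatment", "genotype")]
  routing <- if (is.finite(p_int) && p_int <= alpha) "compare_within_treatment"
             else "compare_between_treatments"
  significant <- any(c(p_int, p_main) <= alpha, na.rm = TRUE)

  mse <- at$`Mean Sq`[rn == "Residuals"]
  dfe <- at$Df[rn == "Residuals"]
  tukey <- list(); letters <- list()
  if (routing == "compare_within_treatment") {
    for (tr in levels(df$treatment)) {
      sub <- df[df$treatment == tr, ]
      means <- tapply(sub$y, sub$genotype, mean)
      ns <- tapply(sub$y, sub$genotype, length)
      pm <- tukey_pairwise_p(means, ns, mse, dfe)
      tukey[[tr]] <- pm
      letters[[tr]] <- compact_letters(pm, alpha)
    }
  } else {
    for (g in levels(df$genotype)) {
      sub <- df[df$genotype == g, ]
      means <- tapply(sub$y, sub$treatment, mean)
      ns <- tapply(sub$y, sub$treatment, length)
      pm <- tukey_pairwise_p(means, ns, mse, dfe, nmeans = 2)
      tukey[[g]] <- pm
      letters[[g]] <- compact_letters(pm, alpha)
    }
  }
  structure(list(response = response, homogeneity_p = hom$p.value,
                 normality_p = norm_p, anova_table = anova_table,
                 routing = routing, significant = significant,
                 tukey = tukey, letters = letters, alpha = alpha),
            class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("Factorial analysis of %s (alpha = %g)\n", x$response, x$alpha))
  print(x$anova_table, row.names = FALSE, digits = 4)
  cat(sprintf("assumptions: Cochran C p = %.3g, Shapiro-Wilk p = %.3g\n",
              x$homogeneity_p, x$normality_p))
  cat("routing:", x$routing, "\n")
  for (f in names(x$letters)) {
    cat(sprintf("  [%s] %s\n", f,
                paste(names(x$letters[[f]]), x$letters[[f]], sep = ":", collapse = "  ")))
  }
  invisible(x)
}

#' Compact letter display
#'
#' Assigns letters to groups so that two groups share a letter if and only if
#' their pairwise adjusted p-value exceeds `alpha`. Each letter corresponds to
#' a clique of the non-significance graph; for up to 8 groups the exact
#' minimum number of letters is found by searching covers built from maximal
#' cliques, beyond that the insert-and-absorb construction is used (split
#' every letter column containing a significant pair, then absorb columns
#' contained in another).
#'
#' @param pairwise_p symmetric matrix of pairwise p-values (diagonal ignored;
#'   `NA` is treated as non-significant).
#' @param alpha significance level.
#' @return named character vector: letter string per group.
#' @export
compact_letters <- function(pairwise_p, alpha = 0.05) {
  p <- as.matrix(pairwise_p)
  g <- nrow(p)
  if (ncol(p) != g) stopf("pairwise_p must be square")
  if (max(abs(p - t(p)), na.rm = TRUE) > 1e-12) stopf("pairwise_p must be symmetric")
  nms <- rownames(p)
  if (is.null(nms)) nms <- as.character(seq_len(g))
  cols <- if (g <= 8) minimal_letter_columns(p, alpha) else
    insert_absorb_columns(p, alpha)
  cols <- cols[order(vapply(cols, function(cc) which(cc)[1], 1))]
  if (length(cols) > 26) stopf("more than 26 letters needed")
  out <- vapply(seq_len(g), function(i) {
    paste(letters[which(vapply(cols, `[`, TRUE, i))], collapse = "")
  }, "")
  names(out) <- nms
  out
}

# adjacency of the non-significance graph (NA counts as non-significant)
ns_adjacency <- function(p, alpha) {
  adj <- is.na(p) | p > alpha
  diag(adj) <- TRUE
  adj
}

# exact minimum letter count: cover all non-significant pairs and all groups
# with as few cliques as possible, searching over maximal cliques only
minimal_letter_columns <- function(p, alpha) {
  g <- nrow(p)
  adj <- ns_adjacency(p, alpha)
  is_clique <- function(s) length(s) < 2 || all(adj[s, s])
  subsets <- lapply(seq_len(2^g - 1), function(m) which(bitwAnd(m, 2^(seq_len(g) - 1)) > 0))
  cl <- Filter(is_clique, subsets)
  maximal <- cl[vapply(cl, function(s) {
    !any(vapply(seq_len(g)[-s], function(v) all(adj[v, s]), TRUE))
  }, TRUE)]
  edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  covers <- function(sel) {
    cover <- maximal[sel]
    if (length(unique(unlist(cover))) < g) return(FALSE)
    if (nrow(edges) == 0) return(TRUE)
    all(apply(edges, 1, function(e) {
      any(vapply(cover, function(s) all(e %in% s), TRUE))
    }))
  }
  for (k in seq_along(maximal)) {
    cand <- utils::combn(length(maximal), k)
    for (j in seq_len(ncol(cand))) {
      if (covers(cand[, j])) {
        return(lapply(maximal[cand[, j]], function(s) seq_len(g) %in% s))
      }
    }
  }
  stopf("internal error: no clique cover found")  # unreachable
}

insert_absorb_columns <- function(p, alpha) {
  g <- nrow(p)
  cols <- list(rep(TRUE, g))
  absorb <- function(cols) {
    drop <- rep(FALSE, length(cols))
    for (i in seq_along(cols)) for (j in seq_along(cols)) {
      if (i != j && !drop[i] && !drop[j] && all(cols[[i]] <= cols[[j]])) {
        # ties (identical columns): drop the later one only
        if (!all(cols[[i]] == cols[[j]]) || i > j) drop[i] <- TRUE
      }
    }
    cols[!drop]
  }
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    if (is.na(p[i, j]) || p[i, j] > alpha) next
    for (k in seq_along(cols)) {
      if (cols[[k]][i] && cols[[k]][j]) {
        c1 <- cols[[k]]; c1[i] <- FALSE
        c2 <- cols[[k]]; c2[j] <- FALSE
        cols[[k]] <- c1
        cols[[length(cols) + 1]] <- c2
      }
    }
    cols <- absorb(cols)
  }
  cols
}

#' Interpret a Pearson correlation coefficient
#'
#' Band mapping on |r|: 0.00-0.30 negligible, 0.30-0.50 low, 0.50-0.70
#' moderate, 0.70-0.90 high, 0.90-1.00 very high; boundaries belong to the
#' upper band. The direction word (positive/negative) follows the sign.
#'
#' @param r numeric vector of correlation coefficients in `[-1, 1]` (NA
#'   allowed).
#' @return character vector of labels like `"moderate positive"`.
#' @export
interpret_r <- function(r) {
  vapply(r, function(x) {
    if (is.na(x)) return(NA_character_)
    if (abs(x) > 1 + 1e-12) stopf("|r| > 1")
    a <- abs(x)
    band <- if (a < 0.30) "negligible" else if (a < 0.50) "low" else
      if (a < 0.70) "moderate" else if (a < 0.90) "high" else "very high"
    sign <- if (x < 0) "negative" else "positive"
    paste(band, sign)
  }, "")
}

#' Pearson correlation report with interpretation bands
#'
#' Pairwise Pearson r and two-sided p over the requested variables
#' (pairwise-complete observations, >= 3 per pair), with the interpretation
#' label of each coefficient.
#'
#' @param records data.frame containing the variables.
#' @param variables character vector of column names (>= 2).
#' @return object of class `"correlation_report"`: `variables`, `r_matrix`,
#'   `p_matrix`, `n_matrix`, `interpretation_matrix`.
#' @export
pearson_report <- function(records, variables) {
  if (length(variables) < 2) stopf("need at least two variables")
  miss <- setdiff(variables, names(records))
  if (length(miss)) stopf("variables not in records: %s", paste(miss, collapse = ", "))
  k <- length(variables)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) n[i, i] <- sum(is.finite(records[[variables[i]]]))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- records[[variables[i]]]; y <- records[[variables[j]]]
    ok <- is.finite(x) & is.finite(y)
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3) {
      warnf("fewer than 3 complete observations for %s vs %s", variables[i], variables[j])
      next
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warnf("zero variance in %s vs %s pair: r undefined", variables[i], variables[j])
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  interp <- matrix(interpret_r(as.vector(r)), k, k, dimnames = dimnames(r))
  structure(list(variables = variables, r_matrix = r, p_matrix = p,
                 n_matrix = n, interpretation_matrix = interp),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Pearson correlation report (", length(x$variables), " variables)\n", sep = "")
  print(round(x$r_matrix, 3))
  invisible(x)
}
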