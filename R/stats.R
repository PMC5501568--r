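#' Attribute-indicator correlation table
#'
#' Pairwise Pearson correlations between every landscape attribute and
#' every microbial indicator over the sampled locations, the point-basis
#' comparison behind zone interpretation.  Aspect enters linearly (in
#' degrees), matching how it is carried in the feature matrix.
#'
#' @param st a sample table (data frame; see [read_sample_table()]).
#' @param attributes,indicators column names; defaults are the columns
#'   of the canonical schema present in `st`.
#' @return An object of class `correlation_table`: matrix `r`
#'   (attributes x indicators, full precision; the print method rounds
#'   to 2 decimals) with `NA` for undefined (constant-column) cells.
#' @export
correlation_table <- function(st,
                              attributes = intersect(landscape_columns(), names(st)),
                              indicators = intersect(indicator_columns(), names(st))) {
  if (nrow(st) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (!length(attributes) || !length(indicators))
    stop("no attribute/indicator columns found", call. = FALSE)
  r <- matrix(NA_real_, length(attributes), length(indicators),
              dimnames = list(attributes, indicators))
  for (a in attributes) for (i in indicators) {
    xa <- st[[a]]; xi <- st[[i]]
    ok <- is.finite(xa) & is.finite(xi)
    if (sum(ok) >= 3L && sd(xa[ok]) > 0 && sd(xi[ok]) > 0)
      r[a, i] <- cor(xa[ok], xi[ok])
  }
  structure(list(r = r, n = nrow(st)), class = "correlation_table")
}

landscape_columns <- function() c("elevation", "slope", "aspect",
                                  "plan_curvature", "emi_hh", "emi_vv")
indicator_columns <- function() c("eoc", "mbc", "tc_pct", "mbn", "tn_pct",
                                  "specific_c_min", "specific_n_min",
                                  "nitrate", "ammonium", "n_min", "c_min",
                                  "mbc_mbn_ratio", "ph", "moisture_gg")

#' @export
print.correlation_table <- function(x, ...) {
  cat(sprintf("<correlation_table> Pearson r over %d locations\n", x$n))
  print(round(x$r, 2))
  invisible(x)
}

#' One-way ANOVA of an indicator across clusters
#'
#' Tests whether the indicator differs among clusters, with all-pairs
#' Tukey HSD comparisons at level `alpha` summarized as compact letters
#' (clusters sharing a letter are not significantly different).  No
#' multiple-testing correction is applied across indicators.
#'
#' @param st sample table with a `cluster` column.
#' @param indicator column name of the indicator tested.
#' @param alpha significance level for the pairwise letters.
#' @return An object of class `cluster_anova`: `F`, `p`, `df`, per-
#'   cluster `means` (mean, SE, n, letter), and the Tukey table.
#' @export
anova_by_cluster <- function(st, indicator, alpha = 0.05) {
  stopifnot("cluster" %in% names(st), indicator %in% names(st))
  v <- st[[indicator]]; g <- factor(st$cluster)
  ok <- is.finite(v)
  v <- v[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop("need >= 2 clusters with >= 2 members each", call. = FALSE)
  means <- tapply(v, g, mean)
  ses <- tapply(v, g, function(z) sd(z) / sqrt(length(z)))
  ns <- as.integer(table(g))
  if (sd(v) == 0) {
    return(structure(list(indicator = indicator, F = NA_real_,
                          p = NA_real_, df = c(NA, NA),
                          means = data.frame(cluster = levels(g),
                                             mean = as.numeric(means),
                                             se = 0, n = ns, letter = "a"),
                          tukey = NULL, alpha = alpha,
                          note = "degenerate: all values equal"),
                     class = "cluster_anova"))
  }
  fit <- aov(v ~ g)
  tab <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  letters <- cld_letters(levels(g), tk[, "p adj"], means, alpha)
  structure(
    list(indicator = indicator,
         F = tab[1L, "F value"], p = tab[1L, "Pr(>F)"],
         df = tab$Df,
         means = data.frame(cluster = levels(g),
                            mean = as.numeric(means),
                            se = as.numeric(ses), n = ns,
                            letter = letters),
         tukey = tk, alpha = alpha, note = NULL),
    class = "cluster_anova")
}

# Compact letter display from pairwise adjusted p-values.  Groups form a
# graph with an edge where the pair is NOT significant; each maximal
# clique gets one letter.  Fine for the handfuls of groups used here.
cld_letters <- function(groups, p_adj, means, alpha) {
  k <- length(groups)
  adj <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (nm in names(p_adj)) {
    pair <- strsplit(nm, "-", fixed = TRUE)[[1L]]
    sig <- is.finite(p_adj[nm]) && p_adj[nm] < alpha
    adj[pair[1L], pair[2L]] <- adj[pair[2L], pair[1L]] <- !sig
  }
  # enumerate maximal all-connected subsets (k is small)
  subsets <- list()
  for (code in seq_len(2^k - 1L)) {
    members <- which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0L)
    if (all(adj[members, members])) subsets[[length(subsets) + 1L]] <- members
  }
  maximal <- Filter(function(s) !any(vapply(subsets, function(t)
    length(t) > length(s) && all(s %in% t), logical(1))), subsets)
  # order letters by descending group mean of each clique
  ord <- order(-vapply(maximal, function(s) max(means[s]), numeric(1)))
  maximal <- maximal[ord]
  lets <- vapply(seq_len(k), function(i) paste(
    letters[which(vapply(maximal, function(s) i %in% s, logical(1)))],
    collapse = ""), character(1))
  lets
}

#' @export
print.cluster_anova <- function(x, ...) {
  cat(sprintf("<cluster_anova> %s: F(%s, %s) = %.3g, p = %.3g\n",
              x$indicator, x$df[1L], x$df[2L], x$F, x$p))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  print(transform(x$means, mean = signif(mean, 4), se = signif(se, 3)))
  invisible(x)
}

#' Does the BMU site represent its cluster mean?
#'
#' For each cluster, a two-sided one-sample Student t-test of the
#' non-BMU members' indicator values against the BMU site's single
#' observation.  (With one observation at the BMU a two-sample test is
#' impossible; the members-vs-BMU-value form is the testable reading.)
#' A significant result means the BMU is a poor stand-in for the cluster
#' mean of that indicator.
#'
#' @param st sample table with `cluster` and a row per design site.
#' @param design the [sampling_design][select_additional_sites()] whose
#'   BMU rows index into `st` (matched by `x`, `y` when `st` has
#'   coordinates, else by row order).
#' @param indicator column name tested.
#' @param alpha significance level for the `different` flag.
#' @return An object of class `bmu_ttest`: data frame with `cluster`,
#'   `bmu_value`, `member_mean`, `t`, `df`, `p`, `different`
#'   (`TRUE`/`FALSE`, or `NA` when members have zero variance).
#' @export
bmu_representativeness <- function(st, design, indicator, alpha = 0.05) {
  stopifnot(inherits(design, "sampling_design"),
            "cluster" %in% names(st), indicator %in% names(st))
  bmu_idx <- match_design_rows(st, design, role = "BMU")
  res <- lapply(seq_along(bmu_idx), function(ci) {
    cl <- design$sites$cluster[design$sites$role == "BMU"][ci]
    bi <- bmu_idx[ci]
    members <- which(st$cluster == st$cluster[bi])
    members <- setdiff(members, bi)
    if (length(members) < 3L)
      stop("cluster ", cl, " needs >= 3 non-BMU members", call. = FALSE)
    mv <- st[[indicator]][members]
    bv <- st[[indicator]][bi]
    if (sd(mv) == 0) {
      data.frame(cluster = cl, bmu_value = bv, member_mean = mean(mv),
                 t = NA_real_, df = NA_real_, p = NA_real_,
                 different = NA)
    } else {
      tt <- t.test(mv, mu = bv)
      data.frame(cluster = cl, bmu_value = bv, member_mean = mean(mv),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, different = tt$p.value < alpha)
    }
  })
  structure(list(indicator = indicator, table = do.call(rbind, res),
                 alpha = alpha),
            class = "bmu_ttest")
}

match_design_rows <- function(st, design, role) {
  s <- design$sites[design$sites$role == role, , drop = FALSE]
  if (all(c("x", "y") %in% names(st))) {
    idx <- vapply(seq_len(nrow(s)), function(i) {
      hit <- which(abs(st$x - s$x[i]) < 1e-6 & abs(st$y - s$y[i]) < 1e-6)
      if (!length(hit))
        stop("design site at (", s$x[i], ", ", s$y[i],
             ") not found in the sample table", call. = FALSE)
      hit[1L]
    }, integer(1))
  } else {
    idx <- s$row
  }
  idx
}

#' @export
print.bmu_ttest <- function(x, ...) {
  cat(sprintf("<bmu_ttest> %s (alpha = %g)\n", x$indicator, x$alpha))
  print(transform(x$table, t = signif(t, 3), p = signif(p, 3)))
  invisible(x)
}

#' Ratios of cluster means
#'
#' Each cluster's indicator mean divided by every other cluster's mean —
#' the effect-size summary used to describe zone contrasts (e.g.
#' "cluster 1 is 1.6 times greater").
#'
#' @param st sample table with a `cluster` column.
#' @param indicator column name.
#' @return An object of class `cluster_ratios`: matrix `ratio` with
#'   `ratio[i, j] = mean_i / mean_j` (full precision; print rounds to 2
#'   decimals), `NA` where the denominator mean is zero.
#' @export
cluster_ratio_summary <- function(st, indicator) {
  stopifnot("cluster" %in% names(st), indicator %in% names(st))
  v <- st[[indicator]]; g <- factor(st$cluster)
  ok <- is.finite(v)
  m <- tapply(v[ok], droplevels(g[ok]), mean)
  k <- length(m)
  ratio <- outer(as.numeric(m), as.numeric(m),
                 function(a, b) ifelse(b == 0, NA_real_, a / b))
  dimnames(ratio) <- list(names(m), names(m))
  structure(list(indicator = indicator, means = m, ratio = ratio),
            class = "cluster_ratios")
}

#' @export
print.cluster_ratios <- function(x, ...) {
  cat(sprintf("<cluster_ratios> %s; cluster means: %s\n", x$indicator,
              paste(signif(x$means, 4), collapse = ", ")))
  print(round(x$ratio, 2))
  invisible(x)
}
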