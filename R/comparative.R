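# Comparative layer: survivor curves over species, taxon medians, log-log
# co-variation fits and classical multidimensional scaling of trait tables.

#' Survivor curve of a trait across species
#'
#' For a set of species trait values, the survivor function at abscissa x is
#' the fraction of species whose value strictly exceeds x.  The curve is a
#' non-increasing step function dropping from 1 towards 0 over the sorted
#' values; its median (where it crosses 0.5) is reported.
#'
#' @param values numeric vector of trait values (one per species).
#' @param name optional trait name used for printing/plotting.
#' @return object of class \code{survivor_curve}: list with sorted
#'   \code{values}, the survivor \code{fraction} just above each value, the
#'   evaluation function \code{fun(x)} and the \code{median}.
#' @export
#' @examples
#' sc <- survivor_curve(c(1, 2, 3))
#' sc$fun(2)   # 1/3: one of three values exceeds 2
survivor_curve <- function(values, name = deparse(substitute(values))) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("survivor_curve needs at least one finite value",
                                call. = FALSE)
  n <- length(values)
  v <- sort(values)
  frac <- 1 - seq_len(n) / n           # fraction strictly exceeding v[i]
  fun <- function(x) vapply(x, function(xi) sum(v > xi) / n, numeric(1))
  out <- list(values = v, fraction = frac, fun = fun,
              median = stats::median(v), n = n, name = name)
  class(out) <- "survivor_curve"
  out
}

#' @export
print.survivor_curve <- function(x, ...) {
  cat(sprintf("survivor curve of '%s': n = %d, median = %g, range [%g, %g]\n",
              x$name, x$n, x$median, min(x$values), max(x$values)))
  invisible(x)
}

#' Plot survivor curves, optionally by taxon
#'
#' @param x a \code{survivor_curve}, or for \code{plot_survivor_curves} a
#'   trait table.
#' @param log plot the abscissa on a log scale (default TRUE for positive
#'   traits).
#' @param ... graphics arguments.
#' @export
plot.survivor_curve <- function(x, log = all(x$values > 0), ...) {
  graphics::plot(x$values, x$fraction, type = "s", ylim = c(0, 1),
                 log = if (log) "x" else "",
                 xlab = x$name, ylab = "fraction of species exceeding", ...)
  graphics::abline(v = x$median, lty = 3)
  invisible(x)
}

#' Survivor curves of one trait for several taxa
#'
#' @param tab a trait table (data.frame with a \code{taxon} column).
#' @param trait column name to plot.
#' @param col colours per taxon.
#' @export
plot_survivor_curves <- function(tab, trait, col = NULL) {
  stopifnot(trait %in% names(tab))
  taxa <- unique(tab$taxon)
  if (is.null(col)) col <- grDevices::hcl.colors(max(2, length(taxa)), "Dark 3")
  vals <- tab[[trait]]
  graphics::plot(NA, xlim = range(vals[vals > 0]), ylim = c(0, 1),
                 log = if (all(vals > 0)) "x" else "",
                 xlab = trait, ylab = "fraction of species exceeding")
  for (i in seq_along(taxa)) {
    sc <- survivor_curve(tab[[trait]][tab$taxon == taxa[i]], name = trait)
    graphics::lines(sc$values, sc$fraction, type = "s", col = col[i])
    graphics::abline(v = sc$median, lty = 3, col = col[i])
  }
  graphics::legend("topright", legend = taxa, col = col[seq_along(taxa)],
                   lty = 1, bty = "n")
  invisible(NULL)
}

#' Taxon medians of a trait
#'
#' Ordinary sample medians (midpoint convention for even n) of one trait per
#' taxon group.
#'
#' @param tab trait table (data.frame with a \code{taxon} column).
#' @param trait trait column name.
#' @param groups taxa to include (default all present).
#' @return named numeric vector of medians.
#' @export
taxon_medians <- function(tab, trait, groups = unique(tab$taxon)) {
  stopifnot(trait %in% names(tab))
  missing_g <- setdiff(groups, unique(tab$taxon))
  if (length(missing_g))
    stop(sprintf("unknown taxon group(s) %s; available: %s",
                 paste(missing_g, collapse = ", "),
                 paste(unique(tab$taxon), collapse = ", ")), call. = FALSE)
  vapply(groups, function(g) stats::median(tab[[trait]][tab$taxon == g]),
         numeric(1))
}

#' Log-log co-variation fit
#'
#' Ordinary least squares of \eqn{\log_{10} y} on \eqn{\log_{10} x}.  With
#' \code{fixed_slope} given, only the intercept is fitted (the reference-line
#' mode used to draw lines of slope 1, -1 or -1.2 through co-variation
#' clouds).
#'
#' @param x,y strictly positive values of equal length (>= 3).
#' @param fixed_slope optional fixed slope.
#' @return list with \code{slope}, \code{intercept} (log10 units),
#'   \code{se_slope} (NA in fixed-slope mode), \code{n}.
#' @export
loglog_fit <- function(x, y, fixed_slope = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  bad <- which(!(is.finite(x) & is.finite(y) & x > 0 & y > 0))
  if (length(bad))
    stop(sprintf("non-positive or non-finite values at rows: %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  lx <- log10(x); ly <- log10(y)
  if (is.null(fixed_slope)) {
    fit <- stats::lm(ly ~ lx)
    se <- suppressWarnings(summary(fit)$coefficients[2, 2])  # 0 for exact laws
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         se_slope = se, n = length(x))
  } else {
    list(slope = fixed_slope, intercept = mean(ly - fixed_slope * lx),
         se_slope = NA_real_, n = length(x))
  }
}

#' The default 15-trait set used for multidimensional scaling
#'
#' Life span, ages at puberty and birth, ultimate length and lengths at
#' puberty and birth, maximum reserve capacity, ultimate reproduction rate,
#' supply stress, precociality, specific somatic maintenance, energy
#' conductance, allocation fraction to soma and the maturities at birth and
#' puberty.
#'
#' @return character vector of trait-table column names.
#' @export
mds_traits <- function() {
  c("a_m", "a_p", "a_b", "L_i", "L_p", "L_b", "E_m", "R_i",
    "s_s", "s_Hbp", "p_M", "v", "kap", "E_Hb", "E_Hp")
}

#' Classical multidimensional scaling of a trait table
#'
#' Standardizes the selected traits (log10 for strictly positive unbounded
#' traits; identity for the dimensionless bounded indices \code{kap},
#' \code{s_s}, \code{s_Hbp}; then z-scoring per column), computes Euclidean
#' distances between species and embeds them by classical (Torgerson) scaling
#' via double-centering and eigendecomposition.  Per-trait Pearson (or
#' Spearman) correlations with the first coordinate summarize which traits
#' drive the separation.
#'
#' @param tab trait table.
#' @param k number of output dimensions (default 2).
#' @param traits trait columns to use (default \code{\link{mds_traits}}).
#' @param cor_method \code{"pearson"} (default) or \code{"spearman"}.
#' @return object of class \code{trait_mds}: list with \code{points}
#'   (species x k, centered), \code{eig} (all eigenvalues, non-increasing),
#'   \code{correlations} (per-trait with coordinate 1), \code{taxon},
#'   \code{traits}, \code{transform} (per-trait transform applied).
#' @export
trait_mds <- function(tab, k = 2, traits = mds_traits(),
                      cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  miss <- setdiff(traits, names(tab))
  if (length(miss))
    stop(sprintf("trait table lacks MDS traits: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  X <- as.matrix(tab[, traits, drop = FALSE])
  if (any(!is.finite(X)))
    stop("non-finite trait values in MDS input", call. = FALSE)
  if (nrow(X) < k + 1) stop("need at least k+1 species", call. = FALSE)
  bounded <- c("kap", "s_s", "s_Hbp")
  transform <- ifelse(traits %in% bounded, "identity", "log10")
  for (j in seq_along(traits)) {
    if (transform[j] == "log10") {
      if (any(X[, j] <= 0))
        stop(sprintf("trait '%s' has non-positive values; cannot log-transform",
                     traits[j]), call. = FALSE)
      X[, j] <- log10(X[, j])
    }
  }
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0] <- 0   # constant columns carry no signal
  D <- stats::dist(Z)
  mds <- stats::cmdscale(D, k = k, eig = TRUE)
  pts <- mds$points
  cors <- apply(Z, 2, function(z)
    if (stats::sd(z) == 0) NA_real_ else
      stats::cor(z, pts[, 1], method = cor_method))
  out <- list(points = pts, eig = mds$eig, correlations = cors,
              taxon = tab$taxon, traits = traits, transform = transform,
              cor_method = cor_method)
  class(out) <- "trait_mds"
  out
}

#' @export
print.trait_mds <- function(x, ...) {
  pos <- x$eig[x$eig > 0]
  cat(sprintf("classical MDS of %d species on %d traits\n",
              nrow(x$points), length(x$traits)))
  cat(sprintf("  first %d eigenvalues carry %.1f%% of positive inertia\n",
              ncol(x$points), 100 * sum(x$eig[seq_len(ncol(x$points))]) / sum(pos)))
  cat("  |correlation| of traits with coordinate 1 (descending):\n")
  cc <- sort(abs(x$correlations), decreasing = TRUE)
  print(round(cc, 3))
  invisible(x)
}

#' @export
plot.trait_mds <- function(x, col = NULL, ...) {
  taxa <- if (is.null(x$taxon)) rep("all", nrow(x$points)) else x$taxon
  u <- unique(taxa)
  if (is.null(col)) col <- grDevices::hcl.colors(max(2, length(u)), "Dark 3")
  graphics::plot(x$points[, 1], x$points[, 2],
                 col = col[match(taxa, u)], pch = 19,
                 xlab = "coordinate 1", ylab = "coordinate 2", ...)
  graphics::legend("topright", legend = u, col = col[seq_along(u)],
                   pch = 19, bty = "n")
  invisible(x)
}
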