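#' Plot a persistence diagram
#'
#' Deaths against births (all births are 0 in a cluster filtration);
#' components that never die are drawn as triangles at the top margin.
#'
#' @param pers a [compute_persistence()] result (or a filtered one).
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the diagram data.frame.
#' @export
plot_persistence_diagram <- function(pers, ...) {
  stopifnot(inherits(pers, "phdms_persistence"))
  d <- pers$diagram
  inf <- is.infinite(d$death)
  ymax <- 1.08
  graphics::plot(NA, xlim = c(-0.02, 1), ylim = c(0, ymax),
                 xlab = "birth", ylab = "death",
                 main = "Persistence diagram", ...)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  graphics::abline(h = 1.04, lty = 3, col = "grey60")
  graphics::points(d$birth[!inf], d$death[!inf], pch = 16, col = "#2166ac")
  if (any(inf))
    graphics::points(d$birth[inf], rep(1.04, sum(inf)), pch = 17,
                     col = "#b2182b")
  invisible(d)
}

spatial_field_plot <- function(spots, value, zlim, main, cex = 0.7) {
  pal <- grDevices::hcl.colors(101, "viridis")
  z <- pmin(pmax((value - zlim[1]) / max(zlim[2] - zlim[1], 1e-12), 0), 1)
  graphics::plot(spots$x, spots$y, pch = 16, cex = cex, asp = 1,
                 col = pal[1 + round(100 * z)],
                 xlab = "x", ylab = "y", main = main)
}

#' Plot a coreness map
#'
#' Spots colored by normalized coreness on a fixed `[0, 1]` scale: the
#' stable core in the high colors, the unstable frontier fading out.
#'
#' @param domain a normalized `multiscale_domain`.
#' @param spots the [spot_set()].
#' @param ... unused.
#' @return Invisibly, the plotted values.
#' @export
plot_coreness_map <- function(domain, spots, ...) {
  stopifnot(inherits(domain, "multiscale_domain"))
  if (is.null(domain$normalized)) domain <- normalize_coreness(domain)
  spatial_field_plot(spots, domain$normalized, c(0, 1),
                     sprintf("Domain %d (lifetime %.3g)", domain$id,
                             domain$lifetime))
  invisible(domain$normalized)
}

#' Plot a heterogeneity map
#'
#' @param h per-spot heterogeneity vector.
#' @param spots the [spot_set()].
#' @param ... unused.
#' @return Invisibly, `h`.
#' @export
plot_heterogeneity_map <- function(h, spots, ...) {
  spatial_field_plot(spots, h, c(0, max(h, 1e-12)), "Heterogeneity")
  invisible(h)
}

#' Plot method for fitted multiscale domains
#'
#' @param x a [phdms()] fit.
#' @param type `"diagram"` (persistence diagram), `"coreness"` (map of one
#'   reported domain) or `"heterogeneity"`.
#' @param domain which reported domain to map (index into the ranked list).
#' @param ... unused.
#' @return Invisibly, `x`.
#' @export
plot.phdms <- function(x, type = c("diagram", "coreness", "heterogeneity"),
                       domain = 1L, ...) {
  type <- match.arg(type)
  switch(type,
         diagram = plot_persistence_diagram(x$kept),
         coreness = plot_coreness_map(x$ranked[[domain]],
                                      x$sequence$spots),
         heterogeneity = plot_heterogeneity_map(x$heterogeneity,
                                                x$sequence$spots))
  invisible(x)
}

#' Render all standard figures of a fit to PNG files
#'
#' One coreness map per reported domain, a heterogeneity map, and the
#' persistence diagram.
#'
#' @param object a [phdms()] fit.
#' @param dir output directory.
#' @param width,height image size in pixels.
#' @return Character vector of files written, invisibly.
#' @export
render_maps <- function(object, dir, width = 800, height = 700) {
  stopifnot(inherits(object, "phdms"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  dev_png <- function(f) grDevices::png(f, width = width, height = height)
  f <- file.path(dir, "persistence_diagram.png")
  dev_png(f); plot_persistence_diagram(object$kept); grDevices::dev.off()
  files <- c(files, f)
  f <- file.path(dir, "heterogeneity.png")
  dev_png(f)
  plot_heterogeneity_map(object$heterogeneity, object$sequence$spots)
  grDevices::dev.off()
  files <- c(files, f)
  for (d in object$ranked) {
    f <- file.path(dir, sprintf("domain_%03d.png", d$id))
    dev_png(f); plot_coreness_map(d, object$sequence$spots)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}
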