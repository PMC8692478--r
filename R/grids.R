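# Clinical error-grid analyses. Clarke zones are the published inequality
# rules; Parkes (consensus) zones for type-1 diabetes are encoded as the
# published boundary polylines, classified from Zone A outward so that
# points exactly on a boundary fall in the lower-risk zone.

#' Clarke error-grid zone of (reference, predicted) pairs
#'
#' Zone A contains predictions within 20% of the reference (or both values
#' in the hypoglycemic range below 70 mg/dL); zones B-E grade increasing
#' clinical risk, E being confusions between hypo- and hyperglycemia.
#' Vectorized; every pair maps to exactly one zone.
#'
#' @param ref reference glucose, mg/dL (0-600).
#' @param pred predicted glucose, mg/dL (0-600).
#' @return character vector of zone letters `"A"`-`"E"`.
#' @export
clarke_zone <- function(ref, pred) {
  abort_if(length(ref) != length(pred), "ref and pred must have equal length")
  abort_if(any(ref < 0 | pred < 0), "glucose values must be non-negative")
  z <- rep("B", length(ref))
  a <- (ref <= 70 & pred <= 70) | abs(ref - pred) <= 0.2 * ref
  e <- (ref >= 180 & pred <= 70) | (ref <= 70 & pred >= 180)
  cc <- (ref >= 70 & ref <= 290 & pred >= ref + 110) |
    (ref >= 130 & ref <= 180 & pred <= (7 / 5) * ref - 182)
  d <- (ref >= 240 & pred >= 70 & pred <= 180) |
    (ref <= 175 / 3 & pred >= 70 & pred <= 180) |
    (ref >= 175 / 3 & ref <= 70 & pred >= (6 / 5) * ref)
  z[d] <- "D"; z[cc] <- "C"; z[e] <- "E"; z[a] <- "A"
  z
}

# Parkes consensus grid, type-1 diabetes: boundary polylines (x = reference,
# y = predicted), published vertex coordinates on the 0-550 mg/dL domain.
# "upper" lines lie above the identity, "lower" lines below; lower lines
# start with a vertical segment at their first x.
parkes_lines_type1 <- function() {
  list(
    upper = list(
      ab = cbind(x = c(0, 30, 140, 280, 430), y = c(50, 50, 170, 380, 550)),
      bc = cbind(x = c(0, 30, 50, 70, 260), y = c(60, 60, 80, 110, 550)),
      cd = cbind(x = c(0, 25, 50, 80, 125), y = c(100, 100, 125, 215, 550)),
      de = cbind(x = c(0, 35, 50), y = c(150, 155, 550))
    ),
    lower = list(
      ab = cbind(x = c(50, 170, 385, 550), y = c(30, 145, 300, 450)),
      bc = cbind(x = c(120, 260, 550), y = c(30, 130, 250)),
      cd = cbind(x = c(250, 550), y = c(40, 150))
    )
  )
}

# y-value of an upper boundary at x; +Inf past the line's end (the boundary
# has left the domain, so it no longer constrains).
parkes_upper_at <- function(x, pts) {
  out <- rep(Inf, length(x))
  inside <- x <= pts[nrow(pts), "x"]
  if (any(inside)) {
    out[inside] <- approx(pts[, "x"], pts[, "y"], xout = x[inside])$y
  }
  out
}

# y-value of a lower boundary at x; 0 at and before the vertical segment, so
# points on the vertical edge classify into the lower-risk zone.
parkes_lower_at <- function(x, pts) {
  out <- rep(0, length(x))
  after <- x > pts[1, "x"]
  if (any(after)) {
    out[after] <- approx(pts[, "x"], pts[, "y"], xout = x[after], rule = 2)$y
  }
  out
}

#' Parkes (consensus) error-grid zone for type-1 diabetes
#'
#' Classifies (reference, predicted) pairs against the published type-1
#' consensus-grid boundaries. Zones are tested from A outward with inclusive
#' bounds, so boundary points land in the lower-risk zone. Values outside
#' the 0-550 mg/dL domain are clamped with a warning.
#'
#' @inheritParams clarke_zone
#' @return character vector of zone letters `"A"`-`"E"`.
#' @export
parkes_zone_type1 <- function(ref, pred) {
  abort_if(length(ref) != length(pred), "ref and pred must have equal length")
  abort_if(any(ref < 0 | pred < 0), "glucose values must be non-negative")
  if (any(ref > 550 | pred > 550)) {
    warning("values above 550 mg/dL clamped to the Parkes grid domain")
    ref <- pmin(ref, 550)
    pred <- pmin(pred, 550)
  }
  ln <- parkes_lines_type1()
  z <- rep("E", length(ref))
  in_band <- function(lo, up) pred >= lo & pred <= up
  a <- in_band(parkes_lower_at(ref, ln$lower$ab), parkes_upper_at(ref, ln$upper$ab))
  b <- in_band(parkes_lower_at(ref, ln$lower$bc), parkes_upper_at(ref, ln$upper$bc))
  cc <- in_band(parkes_lower_at(ref, ln$lower$cd), parkes_upper_at(ref, ln$upper$cd))
  d <- pred <= parkes_upper_at(ref, ln$upper$de)
  z[d] <- "D"; z[cc] <- "C"; z[b] <- "B"; z[a] <- "A"
  z
}

#' Tabulate error-grid zones for a forecast batch
#'
#' @param ref,pred paired glucose values, mg/dL.
#' @param grid `"clarke"` or `"parkes"` (type-1 consensus).
#' @return an `error_grid_result`: zone counts and percentages over `A`-`E`.
#' @export
error_grid <- function(ref, pred, grid = c("clarke", "parkes")) {
  grid <- match.arg(grid)
  z <- if (grid == "clarke") clarke_zone(ref, pred) else parkes_zone_type1(ref, pred)
  counts <- table(factor(z, levels = LETTERS[1:5]))
  structure(list(
    grid = grid,
    zone_counts = as.integer(counts),
    zone_percent = as.numeric(counts) / length(z) * 100,
    zones = LETTERS[1:5], n = length(z)
  ), class = "error_grid_result")
}

#' @rdname error_grid
#' @export
clarke_grid <- function(ref, pred) error_grid(ref, pred, "clarke")

#' @rdname error_grid
#' @export
parkes_grid <- function(ref, pred) error_grid(ref, pred, "parkes")

#' @export
print.error_grid_result <- function(x, ...) {
  cat(sprintf("<%s error grid> n = %d\n", x$grid, x$n))
  print(data.frame(zone = x$zones, count = x$zone_counts,
                   percent = round(x$zone_percent, 2)))
  invisible(x)
}

#' Scatter a forecast on an error grid
#'
#' @param ref,pred paired glucose values, mg/dL.
#' @param grid `"clarke"` or `"parkes"`.
#' @return a ggplot object with the zone boundaries overlaid.
#' @export
plot_error_grid <- function(ref, pred, grid = c("clarke", "parkes")) {
  grid <- match.arg(grid)
  df <- data.frame(ref = ref, pred = pred)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = ref, y = pred)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::coord_fixed(xlim = c(0, 550), ylim = c(0, 550), expand = FALSE) +
    ggplot2::labs(x = "Reference glucose (mg/dL)", y = "Predicted glucose (mg/dL)",
                  title = paste(tools::toTitleCase(grid), "error grid")) +
    ggplot2::theme_minimal()
  seg <- if (grid == "parkes") {
    ln <- parkes_lines_type1()
    do.call(rbind, lapply(c(ln$upper, ln$lower), function(p) {
      data.frame(x = p[-nrow(p), "x"], y = p[-nrow(p), "y"],
                 xend = p[-1, "x"], yend = p[-1, "y"])
    }))
  } else {
    clarke_boundary_segments()
  }
  gg + ggplot2::geom_segment(data = seg,
                             ggplot2::aes(x = x, y = y, xend = xend, yend = yend),
                             inherit.aes = FALSE, colour = "steelblue", linewidth = 0.3)
}

# Boundary segments of the Clarke zones, for plotting only.
clarke_boundary_segments <- function() {
  rbind(
    data.frame(x = 70, y = 0, xend = 70, yend = 56), # A/lower boundary at ref 70
    data.frame(x = 0, y = 70, xend = 58.3, yend = 70),
    data.frame(x = 58.3, y = 70, xend = 70, yend = 84),
    data.frame(x = 70, y = 56, xend = 550, yend = 440), # pred = 0.8 ref
    data.frame(x = 70, y = 84, xend = 458.3, yend = 550), # pred = 1.2 ref
    data.frame(x = 0, y = 180, xend = 70, yend = 180),
    data.frame(x = 70, y = 180, xend = 290, yend = 400),
    data.frame(x = 130, y = 0, xend = 180, yend = 70),
    data.frame(x = 180, y = 0, xend = 180, yend = 70),
    data.frame(x = 240, y = 70, xend = 240, yend = 180),
    data.frame(x = 240, y = 180, xend = 550, yend = 180),
    data.frame(x = 180, y = 70, xend = 550, yend = 70)
  )
}
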