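# Named spherical binding-site regions (the A-E scheme of an ATP pocket) and
# the per-region ring-occupancy distribution table.

#' Construct a region specification
#'
#' @param name character vector of unique region names (declaration order is
#'   kept and breaks assignment ties).
#' @param center numeric matrix (n x 3) of sphere centers in Angstrom.
#' @param radius numeric vector of sphere radii in Angstrom (> 0).
#' @return a `region_spec` (data.frame name, cx, cy, cz, radius).
#' @export
region_spec <- function(name, center, radius) {
  center <- matrix(as.numeric(center), ncol = 3)
  name <- as.character(name)
  radius <- as.numeric(radius)
  if (length(name) != nrow(center) || length(radius) != length(name))
    stop("name, center and radius lengths disagree")
  if (anyDuplicated(name)) stop("duplicate region name: ",
                                name[duplicated(name)][1])
  if (any(radius <= 0)) stop("region radii must be positive")
  if (!all(is.finite(center))) stop("region centers must be finite")
  structure(data.frame(name = name, cx = center[, 1], cy = center[, 2],
                       cz = center[, 3], radius = radius,
                       stringsAsFactors = FALSE),
            class = c("region_spec", "data.frame"))
}

#' Load a region specification from a CSV config
#'
#' Expected columns: `name, center_x, center_y, center_z, radius` (Angstrom).
#'
#' @param path CSV file path.
#' @return a `region_spec`.
#' @export
load_region_spec <- function(path) {
  if (!file.exists(path)) stop("no such region config: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "center_x", "center_y", "center_z", "radius")
  if (!all(need %in% names(df)))
    stop("region config must have columns ", paste(need, collapse = ", "))
  region_spec(df$name, as.matrix(df[, c("center_x", "center_y", "center_z")]),
              df$radius)
}

#' Write a region specification to CSV
#'
#' @param spec a `region_spec`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_spec <- function(spec, path) {
  df <- data.frame(name = spec$name, center_x = spec$cx, center_y = spec$cy,
                   center_z = spec$cz, radius = spec$radius)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build spherical regions from ligand fragment centroids
#'
#' Convenience helper: each region sphere is centred on the centroid of a
#' user-chosen group of ligand atoms. The canonical interface remains the
#' explicit config; this only automates sphere placement.
#'
#' @param ligand_atoms atom data.frame (columns x, y, z).
#' @param groups named list of integer vectors (row indices per region).
#' @param radius sphere radius in Angstrom (default 3.0).
#' @return a `region_spec`.
#' @export
make_region_spec_from_ligand <- function(ligand_atoms, groups, radius = 3.0) {
  centers <- t(vapply(groups, function(ix)
    colMeans(ligand_atoms[ix, c("x", "y", "z"), drop = FALSE]), numeric(3)))
  region_spec(names(groups), centers, rep(radius, length(groups)))
}

#' Assign a point to a region
#'
#' The point goes to the region whose center is nearest among all regions
#' whose sphere contains it; `NA` if no sphere contains it. Exact distance
#' ties are broken by declaration order.
#'
#' @param point xyz vector (or n x 3 matrix for many points).
#' @param spec a `region_spec`.
#' @return region name(s); `NA_character_` where unassigned.
#' @export
assign_region <- function(point, spec) {
  stopifnot(nrow(spec) >= 1)
  pts <- matrix(as.numeric(point), ncol = 3)
  out <- rep(NA_character_, nrow(pts))
  C <- as.matrix(spec[, c("cx", "cy", "cz")])
  for (k in seq_len(nrow(pts))) {
    d <- sqrt(colSums((t(C) - pts[k, ])^2))
    inside <- which(d <= spec$radius)
    if (length(inside) > 0)
      out[k] <- spec$name[inside[which.min(d[inside])]]  # which.min: first wins
  }
  out
}

.distribution_obj <- function(counts, unassigned) {
  total <- sum(counts)
  if (total > 0) {
    ratios <- round_half_away(100 * counts / total, 1)
    warn <- FALSE
  } else {
    ratios <- counts * 0.0
    warn <- TRUE
  }
  structure(list(counts = counts, ratios = ratios, total = total,
                 unassigned = as.integer(unassigned),
                 empty_warning = warn),
            class = "twn_distribution")
}

#' Per-region ring distribution
#'
#' Counts ring centers of mass per region and reports each region's share of
#' the assigned total as a percentage rounded half-away-from-zero to one
#' decimal (table print convention). Rings falling outside every region are
#' excluded from the total and from the ratio denominator, and reported in
#' `unassigned`.
#'
#' @param rings ring table (see [rings_table()]).
#' @param spec a `region_spec`.
#' @return a `twn_distribution`: counts, ratios (%), total, unassigned.
#' @export
twn_distribution <- function(rings, spec) {
  tab <- rings_table(rings)
  counts <- stats::setNames(integer(length(spec$name)), spec$name)
  unassigned <- 0L
  if (nrow(tab) > 0) {
    reg <- assign_region(as.matrix(tab[, c("x", "y", "z")]), spec)
    unassigned <- sum(is.na(reg))
    t0 <- table(factor(reg[!is.na(reg)], levels = spec$name))
    counts[] <- as.integer(t0)
  }
  d <- .distribution_obj(counts, unassigned)
  if (d$empty_warning) warning("no rings assigned to any region; ratios undefined")
  d
}

#' Distribution from pre-tabulated per-region counts
#'
#' Applies the same total/ratio arithmetic as [twn_distribution()] to counts
#' that were tallied elsewhere (e.g. a published occupancy table).
#'
#' @param counts named non-negative integer vector (region -> count).
#' @return a `twn_distribution`.
#' @export
distribution_from_counts <- function(counts) {
  if (is.null(names(counts)) || anyDuplicated(names(counts)))
    stop("counts must be uniquely named by region")
  if (any(counts < 0)) stop("counts must be non-negative")
  .distribution_obj(stats::setNames(as.integer(counts), names(counts)), 0L)
}

#' @export
print.twn_distribution <- function(x, ...) {
  cat(format_distribution(x), sep = "\n")
  invisible(x)
}

#' Format a distribution as a Number / Ratio(%) table
#'
#' @param x a `twn_distribution`.
#' @return character vector of pretty-printed lines.
#' @export
format_distribution <- function(x) {
  lines <- c(sprintf("%-8s %8s %9s", "Region", "Number", "Ratio(%)"))
  for (r in names(x$counts))
    lines <- c(lines, sprintf("%-8s %8d %9.1f", r, x$counts[[r]],
                              x$ratios[[r]]))
  lines <- c(lines, sprintf("%-8s %8d %9.1f", "Total", x$total,
                            if (x$total > 0) 100.0 else 0.0))
  if (x$unassigned > 0)
    lines <- c(lines, sprintf("(%d ring(s) outside all regions, excluded)",
                              x$unassigned))
  lines
}

#' Write a distribution as CSV
#'
#' @param x a `twn_distribution`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_distribution_csv <- function(x, path) {
  df <- data.frame(region = c(names(x$counts), "Total"),
                   number = c(unname(x$counts), x$total),
                   ratio = c(unname(x$ratios), if (x$total > 0) 100.0 else 0.0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
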