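# Synthetic rectangular creekshed domain.
#
# Geometry (printed resolution): the domain is 50 m long-shore (x, columns)
# by 207 m landward (y, rows; row 1 is the seaward boundary). The seaward
# 20 m are the main channel (bed 0 m AMSL at the marsh edge ramping to -6 m
# at the open boundary). A 2 m wide tidal creek runs up the middle of the
# marsh and stops 50 m short of the landward boundary (bed 0.79 m AMSL at
# its head ramping to -1 m at the channel junction). The landward-most
# 50 m x 50 m band is the creekhead, the only zone holding mussel mounds.
# Levees (0.94 m AMSL, 5 m wide) line the channel edge and the creek except
# at the creekhead; 10 m wide levee-adjacent strips come next; everything
# else is platform at 0.79 m AMSL.

ZONE_LEVELS <- c("CHANNEL", "CREEK", "LEVEE", "LEVEE_ADJACENT",
                 "CREEKHEAD", "MUSSEL_MOUND", "PLATFORM")

#' Default vegetation classes
#'
#' Four classes: tall, intermediate and short cordgrass, plus unvegetated.
#' Stem height `h_v` (m), stem density `m_stems` (stems m^-2) and stem
#' diameter `d_s` (m) are editable placeholders standing in for local
#' survey values; the derived density is `n = m_stems * d_s` (m^-1). The
#' unvegetated Chezy `c_b` = 45 m^1/2 s^-1 and drag coefficient `c_d` =
#' 1.65 are shared by all classes.
#'
#' @param tall,intermediate,short Named lists overriding `h_v`, `m_stems`,
#'   `d_s` for a class.
#' @param c_b Unvegetated Chezy coefficient, m^1/2 s^-1.
#' @param c_d Vegetation drag coefficient.
#' @return A data frame, one row per class (`none`, `short`, `intermediate`,
#'   `tall`), with columns `class`, `h_v`, `m_stems`, `d_s`, `n`, and
#'   attributes `c_b`, `c_d`.
#' @export
vegetation_classes <- function(tall = list(h_v = 1.5, m_stems = 200, d_s = 0.010),
                               intermediate = list(h_v = 0.8, m_stems = 300, d_s = 0.005),
                               short = list(h_v = 0.4, m_stems = 500, d_s = 0.002),
                               c_b = 45, c_d = 1.65) {
  mk <- function(cls, p) data.frame(class = cls, h_v = p$h_v,
                                    m_stems = p$m_stems, d_s = p$d_s,
                                    n = p$m_stems * p$d_s)
  out <- rbind(data.frame(class = "none", h_v = 0, m_stems = 0, d_s = 0, n = 0),
               mk("short", short), mk("intermediate", intermediate),
               mk("tall", tall))
  stopifnot(all(out$n[-1] > 0), all(out$h_v[-1] > 0), c_b > 0, c_d > 0)
  attr(out, "c_b") <- c_b
  attr(out, "c_d") <- c_d
  out
}

# split a band of length `len` into rows of height as close to `target` as
# divides exactly; returns the vector of row heights
.band_rows <- function(len, target) {
  n <- max(1L, round(len / target))
  rep(len / n, n)
}

#' Build the standard creekshed model domain
#'
#' Constructs the rectangular 50 m x 207 m creekshed at the printed
#' resolution (50 cm x 50 cm cells in the creekhead band, 50 cm x 100 cm
#' elsewhere) or a coarsened version of it, with zone map, bathymetry,
#' vegetation assignment and mussel-mound layout.
#'
#' @param cell_scale Integer >= 1 coarsening factor applied to the printed
#'   resolution (cell width becomes 0.5 * cell_scale m). The cross-shore
#'   extent (50 m) and the creekhead band must remain divisible.
#' @param mussel_cover Fraction of the creekhead area occupied by mussel
#'   mounds (0-1; the study scenarios use 0, 0.10, 0.20).
#' @param vegetated Logical; if `FALSE` all vegetation classes are absent
#'   (bare-bed friction everywhere).
#' @param veg Vegetation class table from [vegetation_classes()].
#' @param rho_mm Mussel density on mound area, mussels m^-2 (default 177).
#' @param mound_area Footprint of one mound, m^2 (default 0.25; one cell at
#'   printed resolution).
#' @return A `marsh_domain` list: grid geometry (`n_rows`, `n_cols`, `dx`,
#'   `dy`, `y_center`, `x_center`), `zb` bed elevation matrix (m AMSL, row 1
#'   seaward), `zone` integer matrix with levels in `attr(,"zone_levels")`,
#'   `veg_class` integer matrix indexing rows of `veg`, `mound_frac` matrix
#'   (fraction of cell area covered by mounds), `rho_mm_eff` matrix
#'   (effective mussels m^-2 of cell = rho_mm * mound_frac), `mound_count`,
#'   and metadata. Cell values are cell-centred; cell extents half-open.
#' @examples
#' d <- build_paper_domain(cell_scale = 4, mussel_cover = 0.10)
#' zone_areas(d)
#' @export
build_paper_domain <- function(cell_scale = 1, mussel_cover = 0.10,
                               vegetated = TRUE,
                               veg = vegetation_classes(),
                               rho_mm = 177, mound_area = 0.25) {
  stopifnot(cell_scale >= 1, cell_scale == round(cell_scale),
            mussel_cover >= 0, mussel_cover <= 1)
  dx <- 0.5 * cell_scale
  width <- 50; length_m <- 207
  channel_len <- 20; creekhead_len <- 50
  mid_len <- length_m - channel_len - creekhead_len  # 137
  if (abs(width / dx - round(width / dx)) > 1e-9)
    stop(sprintf("cross-shore extent 50 m is not divisible by cell width %g m", dx))
  n_cols <- as.integer(round(width / dx))

  dy_ch <- .band_rows(channel_len, cell_scale * 1.0)
  dy_mid <- .band_rows(mid_len, cell_scale * 1.0)
  dy_head <- .band_rows(creekhead_len, cell_scale * 0.5)
  if (abs(creekhead_len / (0.5 * cell_scale) -
          round(creekhead_len / (0.5 * cell_scale))) > 1e-9)
    stop(sprintf("creekhead band 50 m is not divisible by row height %g m",
                 0.5 * cell_scale))
  dy <- c(dy_ch, dy_mid, dy_head)
  n_rows <- length(dy)
  y_edge <- c(0, cumsum(dy))
  y_center <- (y_edge[-1] + y_edge[-length(y_edge)]) / 2
  x_edge <- seq(0, width, by = dx)
  x_center <- (x_edge[-1] + x_edge[-length(x_edge)]) / 2

  zone <- matrix(match("PLATFORM", ZONE_LEVELS), n_rows, n_cols)
  zb <- matrix(0.79, n_rows, n_cols)

  in_channel <- y_center < channel_len
  creek_y0 <- channel_len; creek_y1 <- channel_len + mid_len
  # creek columns: 2 m wide centred, never fewer than one column
  n_creek_cols <- max(1L, as.integer(round(2 / dx)))
  c0 <- (n_cols - n_creek_cols) %/% 2
  creek_cols <- (c0 + 1):(c0 + n_creek_cols)

  for (j in seq_len(n_rows)) {
    y <- y_center[j]
    if (in_channel[j]) {
      zone[j, ] <- match("CHANNEL", ZONE_LEVELS)
      zb[j, ] <- -6 + (y / channel_len) * 6  # -6 seaward -> 0 at marsh edge
    } else if (y < creek_y1) {
      # marsh band with creek
      zone[j, creek_cols] <- match("CREEK", ZONE_LEVELS)
      frac <- (creek_y1 - y) / mid_len   # 1 at junction -> 0 at head
      zb[j, creek_cols] <- 0.79 - frac * (0.79 - (-1))
      # levee / levee-adjacent by distance from channel or creek
      d_chan <- y - channel_len
      for (i in seq_len(n_cols)) {
        if (i %in% creek_cols) next
        d_creek <- if (i < creek_cols[1]) x_edge[creek_cols[1]] - x_center[i]
                   else x_center[i] - x_edge[creek_cols[length(creek_cols)] + 1]
        d <- min(d_chan, d_creek)
        if (d < 5) {
          zone[j, i] <- match("LEVEE", ZONE_LEVELS)
          zb[j, i] <- 0.94
        } else if (d < 15) {
          zone[j, i] <- match("LEVEE_ADJACENT", ZONE_LEVELS)
        }
      }
    } else {
      zone[j, ] <- match("CREEKHEAD", ZONE_LEVELS)
    }
  }

  # mussel mounds inside the creekhead band
  head_mask <- zone == match("CREEKHEAD", ZONE_LEVELS)
  area_mat <- outer(dy, rep(dx, n_cols))
  pm <- place_mounds(head_mask, mussel_cover, mound_area = mound_area,
                     cell_area = area_mat)
  zone[pm$mask] <- match("MUSSEL_MOUND", ZONE_LEVELS)
  rho_eff <- rho_mm * pm$frac

  veg_class <- matrix(1L, n_rows, n_cols)  # 1 = none
  if (vegetated) {
    idx <- function(cls) match(cls, veg$class)
    veg_class[zone == match("LEVEE", ZONE_LEVELS)] <- idx("tall")
    veg_class[zone == match("LEVEE_ADJACENT", ZONE_LEVELS)] <- idx("intermediate")
    veg_class[zone %in% match(c("PLATFORM", "CREEKHEAD", "MUSSEL_MOUND"),
                              ZONE_LEVELS)] <- idx("short")
    veg_class[zb <= 0] <- idx("none")  # only cells above MSL carry vegetation
  }

  structure(list(n_rows = n_rows, n_cols = n_cols,
                 dx = dx, dy = dy,
                 x_center = x_center, y_center = y_center,
                 cell_area = area_mat,
                 zb = zb, zone = zone,
                 veg = veg, veg_class = veg_class,
                 mound_frac = pm$frac, rho_mm_eff = rho_eff,
                 mound_count = pm$count,
                 mussel_cover = mussel_cover, vegetated = vegetated,
                 cell_scale = cell_scale, rho_mm = rho_mm,
                 zone_levels = ZONE_LEVELS),
            class = "marsh_domain")
}

#' Place mussel mounds on a regular lattice inside the creekhead
#'
#' Mounds are laid out deterministically on a rectangular lattice with
#' alternate-row offset, as uniformly as integer cell geometry allows. The
#' physical mound count is `round(cover * creekhead_area / mound_area)`
#' regardless of grid resolution; on grids whose cells exceed one mound
#' footprint, each lattice cell carries several mounds and the per-cell
#' covered fraction is returned.
#'
#' @param creekhead_mask Logical matrix marking creekhead cells.
#' @param cover Fraction of creekhead area to cover (0-1).
#' @param mound_area Footprint of one mound, m^2.
#' @param cell_area Matrix (or scalar) of cell areas, m^2.
#' @param seed Ignored unless a randomised layout is requested; the default
#'   lattice is deterministic.
#' @param randomize Logical; if `TRUE`, sample mound cells uniformly at
#'   random (seeded) instead of the lattice.
#' @return A list: `mask` (logical matrix of mound cells), `frac` (matrix of
#'   mound-covered fraction per cell), `count` (physical mound count).
#' @export
place_mounds <- function(creekhead_mask, cover, mound_area = 0.25,
                         cell_area = 0.25, seed = NULL, randomize = FALSE) {
  stopifnot(cover >= 0, cover <= 1, mound_area > 0)
  if (length(cell_area) == 1)
    cell_area <- matrix(cell_area, nrow(creekhead_mask), ncol(creekhead_mask))
  frac <- matrix(0, nrow(creekhead_mask), ncol(creekhead_mask))
  mask <- matrix(FALSE, nrow(creekhead_mask), ncol(creekhead_mask))
  head_area <- sum(cell_area[creekhead_mask])
  count <- round(cover * head_area / mound_area)
  if (count == 0)
    return(list(mask = mask, frac = frac, count = 0L))

  target_area <- count * mound_area
  cells <- which(creekhead_mask, arr.ind = TRUE)
  cell_a <- cell_area[creekhead_mask][1]  # creekhead cells are uniform
  k <- ceiling(target_area / cell_a)      # lattice cells needed
  if (k > nrow(cells))
    stop(sprintf("requested %d mound cells but only %d creekhead cells available",
                 k, nrow(cells)))

  rows <- sort(unique(cells[, 1])); cols <- sort(unique(cells[, 2]))
  nr <- length(rows); nc <- length(cols)
  if (randomize) {
    if (!is.null(seed)) set.seed(seed)
    pick <- cells[sample.int(nrow(cells), k), , drop = FALSE]
  } else {
    # search row/col strides whose offset lattice count comes closest to k
    best <- NULL; best_err <- Inf
    for (pr in seq_len(nr)) for (pc in seq_len(nc)) {
      ri <- seq(1, nr, by = pr)
      cnt <- 0
      for (m in seq_along(ri)) {
        off <- if (m %% 2 == 0) max(1L, pc %/% 2) else 0L
        cnt <- cnt + length(seq(1 + off, nc, by = pc))
      }
      if (abs(cnt - k) < best_err ||
          (abs(cnt - k) == best_err && cnt >= k && !is.null(best) && best$cnt < k)) {
        best <- list(pr = pr, pc = pc, cnt = cnt); best_err <- abs(cnt - k)
      }
      if (best_err == 0) break
    }
    pos <- NULL
    ri <- seq(1, nr, by = best$pr)
    for (m in seq_along(ri)) {
      off <- if (m %% 2 == 0) max(1L, best$pc %/% 2) else 0L
      ci <- seq(1 + off, nc, by = best$pc)
      pos <- rbind(pos, cbind(rows[ri[m]], cols[ci]))
    }
    # trim (evenly by index) or pad (first unused creekhead cells) to k
    if (nrow(pos) > k) {
      keep <- unique(round(seq(1, nrow(pos), length.out = k)))
      if (length(keep) < k)   # rounding collisions: top up deterministically
        keep <- sort(union(keep, setdiff(seq_len(nrow(pos)), keep)[
          seq_len(k - length(keep))]))
      pos <- pos[keep, , drop = FALSE]
    } else if (nrow(pos) < k) {
      key <- paste(pos[, 1], pos[, 2])
      avail <- cells[!(paste(cells[, 1], cells[, 2]) %in% key), , drop = FALSE]
      pos <- rbind(pos, avail[seq_len(k - nrow(pos)), , drop = FALSE])
    }
    pick <- pos
  }
  mask[pick] <- TRUE
  frac[pick] <- target_area / (k * cell_a)  # <= 1 by construction of k
  list(mask = mask, frac = frac, count = as.integer(count))
}

#' Zone areas of a domain
#'
#' @param domain A `marsh_domain`.
#' @return A data frame `zone`, `area_m2` (one row per zone present), with
#'   attributes `total_area` and `marsh_area` (total minus channel).
#' @export
zone_areas <- function(domain) {
  stopifnot(inherits(domain, "marsh_domain"))
  lv <- domain$zone_levels
  area <- vapply(seq_along(lv),
                 function(k) sum(domain$cell_area[domain$zone == k]), 0)
  out <- data.frame(zone = lv, area_m2 = area)
  attr(out, "total_area") <- sum(domain$cell_area)
  attr(out, "marsh_area") <- sum(domain$cell_area) -
    area[match("CHANNEL", lv)]
  out
}

#' @export
print.marsh_domain <- function(x, ...) {
  za <- zone_areas(x)
  cat(sprintf("<marsh_domain> %d x %d cells (%.2g m wide, rows %.2g-%.2g m), %.0f m x %.0f m\n",
              x$n_rows, x$n_cols, x$dx, min(x$dy), max(x$dy),
              max(x$x_center) + x$dx / 2, sum(x$dy)))
  cat(sprintf("  mussel cover %.0f%% of creekhead (%d mounds, %d mound cells); %s\n",
              100 * x$mussel_cover, x$mound_count, sum(x$mound_frac > 0),
              if (x$vegetated) "vegetated" else "unvegetated"))
  print(za, row.names = FALSE)
  invisible(x)
}

#' Serialize a domain to delimited text
#'
#' Long-format TSV with one row per cell: indices, centre coordinates (m),
#' bed elevation, zone label, vegetation class and effective mussel density.
#' A `# key: value` header records the grid metadata.
#'
#' @param domain A `marsh_domain`.
#' @param path Output path.
#' @export
write_domain <- function(domain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_rows: %d", domain$n_rows),
               sprintf("# n_cols: %d", domain$n_cols),
               sprintf("# dx_m: %g", domain$dx),
               sprintf("# cell_scale: %g", domain$cell_scale),
               sprintf("# mussel_cover: %g", domain$mussel_cover),
               sprintf("# vegetated: %s", domain$vegetated),
               "# convention: cell-centred values; row 1 = seaward boundary; half-open cell extents"),
             con)
  df <- expand.grid(row = seq_len(domain$n_rows), col = seq_len(domain$n_cols))
  df$y_m <- domain$y_center[df$row]
  df$x_m <- domain$x_center[df$col]
  df$zb_m <- domain$zb[cbind(df$row, df$col)]
  df$zone <- domain$zone_levels[domain$zone[cbind(df$row, df$col)]]
  df$veg_class <- domain$veg$class[domain$veg_class[cbind(df$row, df$col)]]
  df$rho_mm_eff <- domain$rho_mm_eff[cbind(df$row, df$col)]
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
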