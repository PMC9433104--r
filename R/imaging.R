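#' Render a simulated chip into multi-channel image stacks
#'
#' Draws every tracked object as a filled, rotated ellipse into a per-well
#' four-channel stack (effector dye, target dye, annexin-V, bead channel).
#' Bead objects are drawn into the bead channel; the annexin channel is
#' painted with each target's per-frame annexin intensity, so it turns
#' positive only after death onset.
#'
#' @param chip A `chip_dataset` from [simulate_chip()].
#' @param wells Optional character vector of well ids to render (default
#'   all).
#' @param frames Optional integer vector of frames to render (default all).
#' @param pixel_size_um Microns per pixel (default 1).
#' @return A `rendered_chip` list: `images` (named list of
#'   `[h, w, 4, frames]` arrays) and `meta` (pixel size, channel names,
#'   frames rendered, well geometry).
#' @export
render_frames <- function(chip, wells = NULL, frames = NULL,
                          pixel_size_um = 1) {
  stopifnot(inherits(chip, "chip_dataset"))
  L <- chip$config$well_size_um
  if (is.null(wells)) wells <- unique(chip$tracks$well_id)
  if (is.null(frames)) frames <- seq_len(chip$config$n_frames)
  npx <- as.integer(ceiling(L / pixel_size_um))
  cx <- (seq_len(npx) - 0.5) * pixel_size_um  # pixel-center coordinates
  images <- stats::setNames(vector("list", length(wells)), wells)
  for (w in wells) {
    tw <- chip$tracks[chip$tracks$well_id == w, ]
    arr <- array(0.02, dim = c(npx, npx, 4L, length(frames)))
    for (fi in seq_along(frames)) {
      rows <- tw[tw$frame == frames[fi], ]
      for (i in seq_len(nrow(rows))) {
        r <- rows[i, ]
        a <- r$axis_major_um / 2; b <- r$axis_minor_um / 2
        th <- r$orientation_rad
        xs <- which(abs(cx - r$x_um) <= a); ys <- which(abs(cx - r$y_um) <= a)
        if (!length(xs) || !length(ys)) next
        dx <- outer(cx[xs] - r$x_um, rep(1, length(ys)))
        dy <- outer(rep(1, length(xs)), cx[ys] - r$y_um)
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        inside <- (u / a)^2 + (v / b)^2 <= 1
        vals <- switch(r$role,
          effector = c(r$ch_eff, r$ch_tgt, r$ch_annexin, 0.02),
          target = c(r$ch_eff, r$ch_tgt, r$ch_annexin, 0.02),
          bead = c(0.02, 0.02, 0.02, 0.9))
        for (ch in 1:4) {
          tile <- arr[xs, ys, ch, fi]
          tile[inside] <- pmax(tile[inside], vals[ch])
          arr[xs, ys, ch, fi] <- tile
        }
      }
    }
    images[[w]] <- arr
  }
  structure(list(images = images,
                 meta = list(pixel_size_um = pixel_size_um,
                             channels = c("effector", "target",
                                          "annexin", "bead"),
                             frames = frames, well_size_um = L,
                             frame_interval_min =
                               chip$config$frame_interval_min)),
            class = "rendered_chip")
}

#' Segment one multi-channel well tile
#'
#' Threshold segmentation: each of the effector, target and bead channels is
#' binarized (Otsu by default), the union mask is hole-filled and labeled
#' into connected components, and small components are dropped. Objects are
#' classified cell/bead by size exclusion and effector/target by dye
#' dominance; unusually large cells are flagged as possible merges.
#'
#' @param tile Numeric array `[h, w, channels]` with channels (effector dye,
#'   target dye, annexin, bead).
#' @param pixel_size_um Microns per pixel.
#' @param thresholds Optional numeric vector of per-channel thresholds for
#'   channels 1, 2 and 4; `NA` entries fall back to Otsu.
#' @param min_area_um2 Minimum object area retained (default 10).
#' @param bead_area_max_um2 Size-exclusion bound separating beads from cells
#'   (default 40).
#' @param merged_factor A cell whose area exceeds `merged_factor` times the
#'   median cell area in the tile is flagged `merged` (default 1.8).
#' @return Data frame of labeled objects: centroid (`x_um`, `y_um`), areas,
#'   per-channel mean intensities, `role` ("cell"/"bead"), `class`
#'   ("effector"/"target"/NA), `merged`. Zero rows (with a warning) for a
#'   blank tile.
#' @export
segment_frame <- function(tile, pixel_size_um = 1, thresholds = NULL,
                          min_area_um2 = 10, bead_area_max_um2 = 40,
                          merged_factor = 1.8) {
  stopifnot(length(dim(tile)) == 3L, dim(tile)[3] >= 4L)
  mask <- array(FALSE, dim = dim(tile)[1:2])
  for (ch in c(1L, 2L, 4L)) {
    x <- tile[, , ch]
    thr <- if (!is.null(thresholds) && !is.na(thresholds[match(ch, c(1, 2, 4))]))
      thresholds[match(ch, c(1, 2, 4))] else NA_real_
    if (is.na(thr)) {
      if (diff(range(x)) < 0.15) next  # channel effectively blank
      thr <- EBImage::otsu(EBImage::Image(x), range = range(x))
    }
    mask <- mask | (x > thr)
  }
  if (!any(mask)) {
    warning("blank tile: no objects above threshold")
    return(empty_objects())
  }
  lab <- EBImage::bwlabel(EBImage::fillHull(EBImage::Image(mask)))
  labm <- EBImage::imageData(lab)
  idx <- which(labm > 0)
  if (!length(idx)) {
    warning("blank tile: no objects above threshold")
    return(empty_objects())
  }
  lvl <- labm[idx]
  rowpx <- (idx - 1L) %% dim(labm)[1] + 1L
  colpx <- (idx - 1L) %/% dim(labm)[1] + 1L
  area_px <- tabulate(lvl)
  keep <- which(area_px * pixel_size_um^2 >= min_area_um2)
  if (!length(keep)) return(empty_objects())
  agg <- function(v) as.numeric(tapply(v, lvl, mean))
  obj <- data.frame(
    label = seq_along(area_px),
    area_px = area_px,
    area_um2 = area_px * pixel_size_um^2,
    x_um = agg(rowpx - 0.5) * pixel_size_um,
    y_um = agg(colpx - 0.5) * pixel_size_um,
    ch_eff = agg(tile[, , 1][idx]),
    ch_tgt = agg(tile[, , 2][idx]),
    ch_annexin = agg(tile[, , 3][idx]),
    ch_bead = agg(tile[, , 4][idx]))
  obj <- obj[obj$label %in% keep, , drop = FALSE]
  obj <- size_exclusion_classify(obj, bead_area_max_um2)
  obj$class <- ifelse(obj$role == "bead", NA_character_,
                      ifelse(obj$ch_eff > obj$ch_tgt, "effector", "target"))
  cell_area <- obj$area_um2[obj$role == "cell"]
  med <- if (length(cell_area)) stats::median(cell_area) else NA_real_
  obj$merged <- obj$role == "cell" & !is.na(med) &
    obj$area_um2 > merged_factor * med
  rownames(obj) <- NULL
  obj
}

empty_objects <- function() {
  data.frame(label = integer(), area_px = integer(), area_um2 = numeric(),
             x_um = numeric(), y_um = numeric(), ch_eff = numeric(),
             ch_tgt = numeric(), ch_annexin = numeric(), ch_bead = numeric(),
             role = character(), class = character(), merged = logical())
}

#' Classify objects as cells or beads by area
#'
#' Size-exclusion rule: beads are much smaller than cells, so any object
#' with area at most `bead_area_max` is a bead, anything larger a cell.
#'
#' @param objects Data frame with an `area_um2` column.
#' @param bead_area_max Area bound in square microns; should sit between the
#'   typical bead and cell areas.
#' @return `objects` with a `role` column ("bead"/"cell").
#' @export
size_exclusion_classify <- function(objects, bead_area_max = 40) {
  objects$role <- ifelse(objects$area_um2 <= bead_area_max, "bead", "cell")
  objects
}

#' Link per-frame objects into tracks
#'
#' Greedy nearest-neighbor assignment, independently per well and per
#' object class, across ordered frames; candidates are scored against a
#' constant-velocity prediction of each chain, which keeps identities apart
#' when trajectories cross. Chains absent for up to `gap_max` frames may be
#' bridged; objects that cannot be matched within `max_step_um` start new
#' chains.
#'
#' @param objects Data frame with columns `well_id`, `frame`, `x_um`,
#'   `y_um` and a class column `role` (values such as
#'   "effector"/"target"/"bead"); extra columns are carried through.
#' @param max_step_um Maximum centroid displacement between consecutive
#'   linked detections (default 25).
#' @param gap_max Maximum number of missed frames bridged within a chain
#'   (default 1).
#' @return `objects` with an `object_id` column (`<role><k>` within each
#'   well) and a `gaps` attribute (per-chain bridged-frame counts), sorted
#'   by well, object and frame.
#' @export
link_tracks <- function(objects, max_step_um = 25, gap_max = 1) {
  need <- c("well_id", "frame", "x_um", "y_um", "role")
  if (!all(need %in% names(objects)))
    stop("objects must have columns: ", paste(need, collapse = ", "))
  key <- paste(objects$well_id, objects$frame, objects$x_um, objects$y_um)
  if (anyDuplicated(key)) stop("duplicate (frame, object) keys in input")
  # canonical order for permutation invariance
  objects <- objects[order(objects$well_id, objects$frame,
                           objects$x_um, objects$y_um), , drop = FALSE]
  objects$object_id <- NA_character_
  gaps <- integer(0)
  for (w in unique(objects$well_id)) {
    for (cl in unique(objects$role[objects$well_id == w])) {
      sel <- which(objects$well_id == w & objects$role == cl)
      sub <- objects[sel, ]
      chains <- list()  # each: id, x, y, frame, gaps
      next_id <- 1L
      for (f in sort(unique(sub$frame))) {
        fidx <- which(sub$frame == f)
        open <- which(vapply(chains, function(ch)
          f - ch$frame >= 1L && f - ch$frame <= gap_max + 1L, TRUE))
        assigned <- rep(NA_integer_, length(fidx))
        if (length(open)) {
          d <- outer(seq_along(fidx), seq_along(open),
                     Vectorize(function(i, j) {
                       ch <- chains[[open[j]]]
                       lag <- f - ch$frame
                       px <- ch$x + ch$vx * lag  # constant-velocity forecast
                       py <- ch$y + ch$vy * lag
                       sqrt((sub$x_um[fidx[i]] - px)^2 +
                            (sub$y_um[fidx[i]] - py)^2)
                     }))
          while (TRUE) {
            m <- which(d == min(d), arr.ind = TRUE)[1, , drop = TRUE]
            if (!is.finite(d[m[1], m[2]]) || d[m[1], m[2]] > max_step_um) break
            assigned[m[1]] <- open[m[2]]
            d[m[1], ] <- Inf; d[, m[2]] <- Inf
            if (all(!is.finite(d))) break
          }
        }
        for (i in seq_along(fidx)) {
          if (is.na(assigned[i])) {
            chains[[length(chains) + 1L]] <-
              list(id = sprintf("%s%d", substr(cl, 1, 1), next_id),
                   x = sub$x_um[fidx[i]], y = sub$y_um[fidx[i]],
                   vx = 0, vy = 0, frame = f, gaps = 0L)
            next_id <- next_id + 1L
            assigned[i] <- length(chains)
          } else {
            ch <- chains[[assigned[i]]]
            lag <- f - ch$frame
            ch$gaps <- ch$gaps + (lag - 1L)
            ch$vx <- (sub$x_um[fidx[i]] - ch$x) / lag
            ch$vy <- (sub$y_um[fidx[i]] - ch$y) / lag
            ch$x <- sub$x_um[fidx[i]]; ch$y <- sub$y_um[fidx[i]]
            ch$frame <- f
            chains[[assigned[i]]] <- ch
          }
          objects$object_id[sel[fidx[i]]] <- chains[[assigned[i]]]$id
        }
      }
      gaps <- c(gaps, stats::setNames(
        vapply(chains, `[[`, 0L, "gaps"),
        paste(w, vapply(chains, `[[`, "", "id"), sep = ":")))
    }
  }
  objects <- objects[order(objects$well_id, objects$object_id,
                           objects$frame), , drop = FALSE]
  rownames(objects) <- NULL
  attr(objects, "gaps") <- gaps
  objects
}

#' Call annexin-V death onset on a target track
#'
#' The death frame is the first frame of the earliest run of at least `k`
#' consecutive frames whose annexin mean intensity exceeds `threshold`;
#' `NA` if no such run exists. Raising the threshold can only delay (or
#' remove) the call, never advance it.
#'
#' @param chain Data frame for one target track with columns `frame` and
#'   `ch_annexin`.
#' @param threshold Annexin positivity threshold (default 0.5).
#' @param k Required run length in frames (default 2; rejects single-frame
#'   flicker at 5-minute sampling).
#' @return Integer frame number or `NA`.
#' @export
call_death <- function(chain, threshold = 0.5, k = 2) {
  if (is.null(chain) || nrow(chain) == 0L) stop("empty chain")
  ord <- order(chain$frame)
  fr <- chain$frame[ord]
  pos <- chain$ch_annexin[ord] > threshold
  run <- 0L
  for (i in seq_along(pos)) {
    contiguous <- i > 1 && fr[i] == fr[i - 1] + 1L
    run <- if (pos[i]) (if (contiguous) run + 1L else 1L) else 0L
    if (run >= k) return(as.integer(fr[i] - k + 1L))
  }
  NA_integer_
}

#' Per-well endpoint bead intensity summary
#'
#' Summarizes the endpoint cytokine-capture readout as the median over each
#' well's per-bead mean intensities. Wells listed in `wells` but absent
#' from the bead table get a flagged missing value.
#'
#' @param beads Data frame with `well_id` and either `intensity` (endpoint
#'   table) or `ch_bead` (segmented endpoint objects with `role == "bead"`).
#' @param wells Optional character vector of wells to report (default:
#'   wells present in `beads`).
#' @return Data frame: `well_id`, `bead_median`, `n_beads`, `flag`.
#' @export
bead_endpoint_intensity <- function(beads, wells = NULL) {
  if ("intensity" %in% names(beads)) {
    val <- beads$intensity
  } else if ("ch_bead" %in% names(beads)) {
    beads <- beads[beads$role == "bead", , drop = FALSE]
    val <- beads$ch_bead
  } else stop("beads table needs an 'intensity' or 'ch_bead' column")
  med <- tapply(val, beads$well_id, stats::median)
  n <- tapply(val, beads$well_id, length)
  out <- data.frame(well_id = names(med), bead_median = as.numeric(med),
                    n_beads = as.integer(n), stringsAsFactors = FALSE)
  if (!is.null(wells)) {
    miss <- setdiff(wells, out$well_id)
    if (length(miss))
      out <- rbind(out, data.frame(well_id = miss, bead_median = NA_real_,
                                   n_beads = 0L))
    out <- out[match(wells, out$well_id), , drop = FALSE]
  }
  out$flag <- ifelse(out$n_beads == 0L, "no_beads", NA_character_)
  rownames(out) <- NULL
  out
}

#' Match endpoint wells to time-lapse wells
#'
#' Inner join on `well_id`; wells present on only one side are reported in
#' the `unmatched_timelapse` / `unmatched_endpoint` attributes.
#'
#' @param timelapse,endpoint Data frames keyed by a unique `well_id`.
#' @return Joined data frame with unmatched wells as attributes.
#' @export
match_endpoint_to_timelapse <- function(timelapse, endpoint) {
  if (anyDuplicated(timelapse$well_id)) stop("duplicate well_id in timelapse")
  if (anyDuplicated(endpoint$well_id)) stop("duplicate well_id in endpoint")
  joined <- merge(timelapse, endpoint, by = "well_id", sort = TRUE)
  attr(joined, "unmatched_timelapse") <-
    sort(setdiff(timelapse$well_id, endpoint$well_id))
  attr(joined, "unmatched_endpoint") <-
    sort(setdiff(endpoint$well_id, timelapse$well_id))
  joined
}

#' Segment and link an entire rendered chip back into tracks
#'
#' Runs [segment_frame()] on every rendered well and frame, classifies
#' objects, and links them into tracks with [link_tracks()], producing a
#' table with the same schema as the simulator's track output (role in
#' effector/target/bead).
#'
#' @param rendered A `rendered_chip` from [render_frames()].
#' @inheritParams segment_frame
#' @inheritParams link_tracks
#' @return Track data frame: `well_id`, `object_id`, `role`, `frame`,
#'   `t_min`, `x_um`, `y_um`, `area_um2`, channel means, `merged`.
#' @export
segment_chip <- function(rendered, thresholds = NULL, min_area_um2 = 10,
                         bead_area_max_um2 = 40, max_step_um = 25,
                         gap_max = 1) {
  stopifnot(inherits(rendered, "rendered_chip"))
  px <- rendered$meta$pixel_size_um
  dt <- rendered$meta$frame_interval_min %||% 5
  out <- list()
  for (w in names(rendered$images)) {
    arr <- rendered$images[[w]]
    for (fi in seq_along(rendered$meta$frames)) {
      obj <- suppressWarnings(
        segment_frame(arr[, , , fi], pixel_size_um = px,
                      thresholds = thresholds, min_area_um2 = min_area_um2,
                      bead_area_max_um2 = bead_area_max_um2))
      if (!nrow(obj)) next
      obj$well_id <- w
      obj$frame <- rendered$meta$frames[fi]
      out[[length(out) + 1L]] <- obj
    }
  }
  if (!length(out)) return(empty_objects())
  objects <- do.call(rbind, out)
  objects$role <- ifelse(objects$role == "bead", "bead", objects$class)
  objects$t_min <- (objects$frame - 1) * dt
  link_tracks(objects, max_step_um = max_step_um, gap_max = gap_max)
}
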