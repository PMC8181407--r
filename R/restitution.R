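# Distances (Euclidean and mesh-geodesic), peak-to-peak amplitudes,
# propagation speed, and restitution-curve assembly.

#' Peak-to-peak voltage within a window
#'
#' @param x numeric trace.
#' @param window 0-based half-open `c(start, end)` window; `NULL` uses the
#'   whole trace.
#' @return `max - min` in the window (mV).
#' @export
peakToPeak <- function(x, window = NULL) {
  if (!is.null(window)) {
    .stop_if_not(window[2] > window[1], "empty window")
    x <- x[(window[1] + 1L):min(window[2], length(x))]
  }
  .stop_if_not(length(x) > 0, "empty window")
  max(x) - min(x)
}

#' Read a triangulated surface mesh (ASCII PLY or OFF)
#'
#' Minimal reader for the two plain-text mesh formats; vertices in mm.
#'
#' @param path file path; format inferred from the extension or header.
#' @return a `SurfaceMesh` list: `vertices` (n x 3), `triangles` (m x 3,
#'   1-based vertex indices).
#' @export
readSurfaceMesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- toupper(trimws(lines[1]))
  if (startsWith(header, "PLY")) {
    endh <- grep("^end_header", lines)[1]
    nv <- as.integer(sub(".*element vertex\\s+", "",
                         grep("element vertex", lines[1:endh],
                              value = TRUE)[1]))
    nf <- as.integer(sub(".*element face\\s+", "",
                         grep("element face", lines[1:endh],
                              value = TRUE)[1]))
    vl <- lines[(endh + 1L):(endh + nv)]
    fl <- lines[(endh + nv + 1L):(endh + nv + nf)]
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                   function(z) as.numeric(z[1:3])))
    tris <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(z) {
      z <- as.integer(z); .stop_if_not(z[1] == 3L,
                                       "only triangle meshes supported")
      z[2:4] + 1L
    }))
  } else if (startsWith(header, "OFF")) {
    counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    nv <- counts[1]; nf <- counts[2]
    vl <- lines[3:(2 + nv)]
    fl <- lines[(3 + nv):(2 + nv + nf)]
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                   function(z) as.numeric(z[1:3])))
    tris <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(z) {
      z <- as.integer(z); .stop_if_not(z[1] == 3L,
                                       "only triangle meshes supported")
      z[2:4] + 1L
    }))
  } else stop("unsupported mesh format (ASCII PLY or OFF expected)")
  structure(list(vertices = verts, triangles = tris), class = "SurfaceMesh")
}

# Shortest vertex-path length over mesh edges between the vertices nearest
# two query points.
.geodesic_distance <- function(mesh, a, b) {
  v <- mesh$vertices
  tri <- mesh$triangles
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  w <- sqrt(rowSums((v[edges[, 1], , drop = FALSE] -
                     v[edges[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  ia <- which.min(colSums((t(v) - a)^2))
  ib <- which.min(colSums((t(v) - b)^2))
  d <- igraph::distances(g, v = ia, to = ib, weights = w)[1, 1]
  .stop_if_not(is.finite(d), "mesh is disconnected between the endpoints")
  d
}

#' Distance between two bipoles
#'
#' Euclidean distance within a single catheter; geodesic distance (shortest
#' vertex path over the mesh edges) across catheters when a mesh is given,
#' since the wave travels along the atrial wall. Without a mesh, `auto`
#' falls back to the Euclidean distance.
#'
#' @param rec an [EgmRecording-class] with geometry.
#' @param a,b channel indices or names.
#' @param mesh optional [readSurfaceMesh()] result.
#' @param mode `"auto"`, `"euclidean"` or `"geodesic"`.
#' @return distance in mm.
#' @export
bipoleDistance <- function(rec, a, b, mesh = NULL,
                           mode = c("auto", "euclidean", "geodesic")) {
  mode <- match.arg(mode)
  if (is.character(a)) a <- match(a, channelNames(rec))
  if (is.character(b)) b <- match(b, channelNames(rec))
  pa <- bipolePosition(rec, a); pb <- bipolePosition(rec, b)
  same <- rec@catheter[a] == rec@catheter[b]
  if (mode == "auto") mode <- if (same || is.null(mesh)) "euclidean"
                              else "geodesic"
  if (mode == "geodesic") {
    .stop_if_not(!is.null(mesh), "geodesic distance requires a mesh")
    return(.geodesic_distance(mesh, pa, pb))
  }
  sqrt(sum((pa - pb)^2))
}

#' Propagation speed from distance and activation time
#'
#' The scalar projection surrogate of conduction velocity: distance from
#' the stimulation site divided by the local activation time. Not the true
#' wavefront velocity, but directly comparable across rates.
#'
#' @param distance_mm distance in mm (0 for the stimulating bipole itself:
#'   returns 0 with a `degenerate` attribute).
#' @param lat_ms activation delay in ms; must be positive.
#' @return speed in mm/s.
#' @export
propagationSpeed <- function(distance_mm, lat_ms) {
  .stop_if_not(all(lat_ms > 0), "non-causal activation: LAT must be > 0")
  p <- 1000 * distance_mm / lat_ms
  if (any(distance_mm == 0)) attr(p, "degenerate") <- which(distance_mm == 0)
  p
}

#' Assemble restitution curves from detections
#'
#' Per channel, maps the S2 coupling interval to the response amplitude
#' (peak-to-peak), the propagation speed (stimulating-bipole distance over
#' LAT), and the LAT itself. Refractory trains and undetected beats are
#' omitted; the stimulating channel and (by default) its neighbors are
#' omitted. Points deviating more than `outlier_sd` standard deviations
#' from their channel's curve are flagged, not removed.
#'
#' @param detections detection table from [runPipeline()]/[analyzeChannel()].
#' @param protocol a `ProtocolEstimate`.
#' @param rec the recording (for geometry).
#' @param mesh optional surface mesh for inter-catheter distances.
#' @param refractory logical per train (from [estimateErp()]); refractory
#'   trains are dropped.
#' @param exclude_neighbors drop channels neighboring the stimulating
#'   bipole.
#' @param outlier_sd flag threshold in channel-curve standard deviations.
#' @return tidy data frame: `channel`, `channel_name`, `catheter`,
#'   `quantity` (`amplitude`, `propagation_speed`, `lat`), `s2_ms`,
#'   `value`, `outlier`.
#' @export
buildCurves <- function(detections, protocol, rec, mesh = NULL,
                        refractory = NULL, exclude_neighbors = TRUE,
                        outlier_sd = 3) {
  fs <- samplingRate(rec)
  stim_ch <- protocol$stim_channel
  d <- detections[detections$label == "S2" & detections$detected, ,
                  drop = FALSE]
  if (!is.null(refractory) && any(refractory %in% TRUE)) {
    bad <- which(refractory %in% TRUE)
    d <- d[!(d$train %in% bad), , drop = FALSE]
  }
  keep_ch <- setdiff(unique(d$channel), stim_ch)
  if (exclude_neighbors && !isGeometryFree(rec)) {
    pos <- t(vapply(seq_len(nChannels(rec)),
                    function(i) bipolePosition(rec, i), numeric(3)))
    same <- which(rec@catheter == rec@catheter[stim_ch])
    dd <- sqrt(colSums((t(pos[same, , drop = FALSE]) - pos[stim_ch, ])^2))
    lim <- 1.25 * min(dd[dd > 0])
    nbr <- same[dd > 0 & dd <= lim]
    keep_ch <- setdiff(keep_ch, nbr)
  }
  rows <- lapply(keep_ch, function(ch) {
    dc <- d[d$channel == ch, , drop = FALSE]
    if (nrow(dc) == 0L) return(NULL)
    dist <- bipoleDistance(rec, stim_ch, ch, mesh = mesh)
    sp <- propagationSpeed(dist, dc$lat_ms)
    base <- dc[order(-dc$s2_ms), c("channel", "channel_name", "catheter",
                                   "s2_ms")]
    ord <- order(-dc$s2_ms)
    rbind(
      cbind(base, quantity = "amplitude", value = dc$amplitude[ord]),
      cbind(base, quantity = "propagation_speed", value = sp[ord]),
      cbind(base, quantity = "lat", value = dc$lat_ms[ord]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$outlier <- FALSE
  for (ch in unique(out$channel)) for (q in unique(out$quantity)) {
    i <- out$channel == ch & out$quantity == q
    if (sum(i) >= 3L) {
      z <- out$value[i]
      out$outlier[i] <- abs(z - mean(z)) > outlier_sd * sd(z)
    }
  }
  rownames(out) <- NULL
  out[, c("channel", "channel_name", "catheter", "quantity", "s2_ms",
          "value", "outlier")]
}

#' Fit a saturating-exponential restitution curve
#'
#' Convenience three-parameter least-squares fit
#' `value = A - B * exp(-s2 / tau)`; `A` estimates the curve's asymptote.
#'
#' @param s2_ms coupling intervals (ms).
#' @param value curve values.
#' @return named coefficients `A`, `B`, `tau`, or `NULL` when the fit fails.
#' @export
fitRestitution <- function(s2_ms, value) {
  a0 <- max(value); b0 <- max(a0 - min(value), 1e-6); t0 <- 60
  fit <- try(suppressWarnings(
    nls(value ~ A - B * exp(-s2_ms / tau),
        start = list(A = a0, B = b0, tau = t0),
        control = stats::nls.control(maxiter = 500, warnOnly = TRUE))),
    silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  coef(fit)
}
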