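#' Watershed parcel label map
#'
#' 3D integer labelling of the suprathreshold voxels of a statistic map:
#' label 0 is exactly the subthreshold background, labels 1..K partition the
#' suprathreshold set, numbered in decreasing order of region peak
#' statistic.
#'
#' @slot labels 3D integer array.
#' @slot threshold statistic threshold that defined the background.
#' @slot mergeThreshold minimum region size, voxels.
#' @slot seedRadius basin seed radius, voxels (Euclidean, voxel units).
#' @slot peaks data.frame: label, peak statistic and peak voxel coordinates.
#' @exportClass ParcelLabelMap
setClass("ParcelLabelMap",
  representation(labels = "array", threshold = "numeric",
                 mergeThreshold = "integer", seedRadius = "numeric",
                 peaks = "data.frame"))

setMethod("show", "ParcelLabelMap", function(object) {
  k <- max(object@labels)
  cat(sprintf("ParcelLabelMap: %d region(s) on a %s grid (thr %.2f, merge %d, radius %.0f)\n",
              k, paste(dim(object@labels), collapse = " x "),
              object@threshold, object@mergeThreshold, object@seedRadius))
})

#' @rdname accessors
#' @export
setGeneric("parcelLabels", function(object) standardGeneric("parcelLabels"))

#' @rdname accessors
#' @export
setMethod("parcelLabels", "ParcelLabelMap", function(object) object@labels)

# 26-connected neighbour offsets in 3D
neighbour_offsets <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

#' Watershed parcellation of a 3D statistic map
#'
#' Partitions the suprathreshold voxels of a continuous map into regions by
#' an invert-rank-flood watershed. The map is inverted so that peaks sit at
#' the bottom of valleys, voxels are ranked (ties broken by voxel
#' coordinate) and flooded in rank order. Each voxel takes one of four
#' outcomes: (1) a voxel within `seedRadius` (Euclidean, voxel units) of an
#' existing basin seed joins that basin; (2) a voxel with no labelled
#' 26-neighbours seeds a new basin; (3) a voxel with labelled neighbours is
#' assigned winner-takes-all to the neighbouring basin whose seed statistic
#' is highest (ties to the smaller label); (4) after flooding, any region
#' smaller than `mergeThreshold` voxels that touches another region is
#' merged into its highest-seed neighbour, smallest regions first, until a
#' fixed point. Labels are then renumbered 1..K by decreasing peak
#' statistic.
#'
#' @param map 3D numeric array of statistic values (finite).
#' @param threshold background threshold; voxels with `map <= threshold`
#'   are background.
#' @param mergeThreshold minimum region size, voxels (default 100).
#' @param seedRadius basin seed radius, voxels (default 5).
#' @return a [ParcelLabelMap-class].
#' @export
watershedParcellate <- function(map, threshold, mergeThreshold = 100L,
                                seedRadius = 5) {
  stopifnot(length(dim(map)) == 3, all(is.finite(map)))
  dims <- dim(map)
  supra <- which(map > threshold)
  if (length(supra) == 0)
    stop("no suprathreshold voxels: nothing to parcellate")
  vals <- map[supra]
  ord <- order(-vals, supra)          # rank 1 = global peak; ties by coordinate
  supra <- supra[ord]
  vals <- vals[ord]
  coords <- arrayInd(supra, dims)
  nsup <- length(supra)
  pos <- integer(prod(dims))          # supra index by linear voxel index
  pos[supra] <- seq_len(nsup)

  offs <- neighbour_offsets()
  # supra-neighbour table (nsup x 26, 0 = background or out of bounds),
  # computed once and reused for flooding and merge adjacency
  NB <- matrix(0L, nsup, nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nx <- coords[, 1] + offs[o, 1]
    ny <- coords[, 2] + offs[o, 2]
    nz <- coords[, 3] + offs[o, 3]
    ok <- nx >= 1 & nx <= dims[1] & ny >= 1 & ny <= dims[2] &
          nz >= 1 & nz <= dims[3]
    lin <- nx[ok] + (ny[ok] - 1L) * dims[1] + (nz[ok] - 1L) * dims[1] * dims[2]
    NB[ok, o] <- pos[lin]
  }
  nb <- lapply(seq_len(nsup), function(k) { v <- NB[k, ]; v[v > 0L] })

  lab <- integer(nsup)
  seed_xyz <- matrix(0, 0, 3)
  seed_stat <- numeric(0)
  r2 <- seedRadius^2
  for (k in seq_len(nsup)) {
    assigned <- 0L
    if (nrow(seed_xyz)) {
      d2 <- (seed_xyz[, 1] - coords[k, 1])^2 +
            (seed_xyz[, 2] - coords[k, 2])^2 +
            (seed_xyz[, 3] - coords[k, 3])^2
      near <- which(d2 <= r2)
      if (length(near)) {
        best <- near[order(-seed_stat[near], near)][1]
        assigned <- best
      }
    }
    if (assigned == 0L) {
      nl <- unique(lab[nb[[k]]])
      nl <- nl[nl > 0L]
      if (length(nl) == 0L) {
        seed_xyz <- rbind(seed_xyz, coords[k, ])
        seed_stat <- c(seed_stat, vals[k])
        assigned <- length(seed_stat)
      } else {
        assigned <- nl[order(-seed_stat[nl], nl)][1]
      }
    }
    lab[k] <- assigned
  }

  # merge small regions into their strongest-seed neighbour; adjacency is
  # evaluated on a voxel-level pair list built once
  ks <- rep(seq_len(nsup), ncol(NB))
  nbv <- as.vector(NB)
  keep <- nbv > ks
  pa <- ks[keep]; pb <- nbv[keep]
  repeat {
    sizes <- tabulate(lab)
    la <- lab[pa]; lb <- lab[pb]
    cross <- la != lb
    la <- la[cross]; lb <- lb[cross]
    touching <- unique(c(la, lb))
    small <- touching[sizes[touching] < mergeThreshold]
    if (length(small) == 0) break
    cand <- small[order(sizes[small], small)][1]
    nbrs <- unique(c(lb[la == cand], la[lb == cand]))
    into <- nbrs[order(-seed_stat[nbrs], nbrs)][1]
    lab[lab == cand] <- into
  }

  # renumber 1..K by decreasing peak statistic
  peak_stat <- tapply(vals, lab, max)
  ord_lab <- as.integer(names(sort(peak_stat, decreasing = TRUE)))
  remap <- integer(max(lab))
  remap[ord_lab] <- seq_along(ord_lab)
  lab <- remap[lab]

  out <- array(0L, dims)
  out[supra] <- lab
  peaks <- do.call(rbind, lapply(seq_along(ord_lab), function(newl) {
    inr <- which(lab == newl)
    top <- inr[which.max(vals[inr])]
    data.frame(label = newl, peak_stat = vals[top],
               x = coords[top, 1], y = coords[top, 2], z = coords[top, 3])
  }))
  new("ParcelLabelMap", labels = out, threshold = threshold,
      mergeThreshold = as.integer(mergeThreshold), seedRadius = seedRadius,
      peaks = peaks)
}

#' Assign anatomical and network labels to watershed regions
#'
#' Each watershed region takes the anatomical and network labels of the
#' atlas parcel with which it shares the most voxels. Regions overlapping
#' only atlas background are labelled `"unassigned"`.
#'
#' @param parcels a [ParcelLabelMap-class].
#' @param map the statistic map the parcels came from (same grid).
#' @param atlasVolume 3D integer atlas label array on the same grid.
#' @param atlasLookup data.frame with columns `atlas_id`,
#'   `anatomical_name`, `network_17`, `network_7`.
#' @return data.frame: one row per region with label id, anatomical name,
#'   17- and 7-network assignment, size, peak statistic and peak
#'   coordinate.
#' @export
labelToTable <- function(parcels, map, atlasVolume, atlasLookup) {
  labs <- parcels@labels
  if (!all(dim(labs) == dim(atlasVolume)) || !all(dim(labs) == dim(map)))
    stop("parcels, map and atlas volume are on different voxel grids")
  ids <- sort(unique(labs[labs > 0]))
  rows <- lapply(ids, function(id) {
    vox <- labs == id
    at <- table(atlasVolume[vox])
    winner <- as.integer(names(at)[order(-at, as.integer(names(at)))][1])
    pk <- parcels@peaks[parcels@peaks$label == id, ]
    if (winner == 0L || !(winner %in% atlasLookup$atlas_id)) {
      anat <- "unassigned"; n17 <- "unassigned"; n7 <- "unassigned"
    } else {
      lk <- atlasLookup[atlasLookup$atlas_id == winner, ]
      anat <- lk$anatomical_name[1]
      n17 <- lk$network_17[1]
      n7 <- lk$network_7[1]
    }
    data.frame(label_id = id, anatomical_name = anat, network_17 = n17,
               network_7 = n7, n_voxels = sum(vox),
               peak_statistic = pk$peak_stat,
               peak_coordinate = paste(pk$x, pk$y, pk$z, sep = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
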