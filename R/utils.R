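# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_if_not_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Label connected components slice-wise (8-connected in-plane) with ids
# unique across the whole stack.
label_slices <- function(mask) {
  dm <- dim(mask)
  l <- EBImage::bwlabel(mask * 1)  # per-frame labels, restart each slice
  l <- array(as.integer(round(l)), dm)
  lm <- matrix(l, dm[1] * dm[2], dm[3])
  per_max <- vapply(seq_len(dm[3]), function(k) max(lm[, k]), integer(1))
  off <- cumsum(c(0L, head(per_max, -1L)))
  offv <- rep(off, each = dm[1] * dm[2])
  sel <- l > 0L
  l[sel] <- l[sel] + offv[sel]
  l
}

# 3D connected-component labelling: 8-connected within axial slices, merged
# across adjacent slices by voxel overlap (union-find).
label_components_3d <- function(mask) {
  dm <- dim(mask)
  nz <- dm[3]
  labs <- label_slices(mask)
  offset <- max(labs)
  if (offset == 0L) return(labs)
  parent <- seq_len(offset)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  lm <- matrix(labs, dm[1] * dm[2], nz)
  key_base <- offset + 1
  for (k in seq_len(nz - 1L)) {
    a <- lm[, k]
    b <- lm[, k + 1L]
    sel <- a > 0L & b > 0L
    if (!any(sel)) next
    keys <- unique(as.numeric(a[sel]) * key_base + b[sel])
    pa <- as.integer(keys %/% key_base)
    pb <- as.integer(keys %% key_base)
    for (i in seq_along(keys)) {
      ra <- find_root(pa[i])
      rb <- find_root(pb[i])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(offset), find_root, integer(1))
  # compact root ids to 1..n
  uid <- sort(unique(root))
  remap <- integer(offset)
  remap[uid] <- seq_along(uid)
  comp <- remap[root]
  pos <- labs > 0L
  labs[pos] <- comp[labs[pos]]
  labs
}

largest_component_3d <- function(mask) {
  labs <- label_components_3d(mask)
  if (!any(labs > 0L)) return(array(FALSE, dim(mask)))
  sizes <- tabulate(labs[labs > 0L])
  labs == which.max(sizes)
}

remove_small_components_3d <- function(mask, min_voxels) {
  if (min_voxels <= 1L || !any(mask)) return(mask)
  labs <- label_components_3d(mask)
  sizes <- tabulate(labs[labs > 0L])
  keep <- which(sizes >= min_voxels)
  array(labs %in% keep, dim(mask))
}

# Slice-wise binary morphology on whole stacks: EBImage applies a 2D
# structuring element frame by frame on 3D arrays.
disc_brush <- function(radius_px) {
  EBImage::makeBrush(2L * max(1L, radius_px) + 1L, shape = "disc")
}

close_slices <- function(x, brush) {
  array(as.numeric(EBImage::closing(x * 1, brush)) > 0.5, dim(x))
}

fill_slices <- function(x) {
  array(as.numeric(EBImage::fillHull(x * 1)) > 0.5, dim(x))
}

dilate_slices <- function(x, brush) {
  array(as.numeric(EBImage::dilate(x * 1, brush)) > 0.5, dim(x))
}

erode_slices <- function(x, brush) {
  array(as.numeric(EBImage::erode(x * 1, brush)) > 0.5, dim(x))
}
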