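## internal helpers: 6-connected flood fill on logical voxel arrays, local RNG

## linear-index neighbours under 6-connectivity for an nx x ny x nz grid
neighbor_indices <- function(idx, grid) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  i <- (idx - 1L) %% nx
  j <- ((idx - 1L) %/% nx) %% ny
  k <- (idx - 1L) %/% (nx * ny)
  out <- c(idx[i > 0L] - 1L, idx[i < nx - 1L] + 1L,
           idx[j > 0L] - nx, idx[j < ny - 1L] + nx,
           idx[k > 0L] - nx * ny, idx[k < nz - 1L] + nx * ny)
  out
}

## set of voxels reachable from `seeds` through TRUE voxels of `mask`
flood_reach <- function(mask, seeds, grid) {
  visited <- logical(length(mask))
  frontier <- seeds[mask[seeds]]
  visited[frontier] <- TRUE
  while (length(frontier)) {
    nb <- unique(neighbor_indices(frontier, grid))
    nb <- nb[mask[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

## number of 6-connected components of TRUE voxels
count_components <- function(mask) {
  grid <- dim(mask)
  m <- as.logical(mask)
  todo <- which(m)
  ncomp <- 0L
  remaining <- m
  while (length(todo)) {
    ncomp <- ncomp + 1L
    reach <- flood_reach(remaining, todo[1L], grid)
    remaining[reach] <- FALSE
    todo <- todo[!reach[todo]]
  }
  ncomp
}

## linear indices of the bottom (k = 1) and top (k = nz) voxel layers
face_layer_indices <- function(grid, which = c("bottom", "top")) {
  which <- match.arg(which)
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  k <- if (which == "bottom") 0L else nz - 1L
  as.integer(k * nx * ny + seq_len(nx * ny))
}

## evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
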