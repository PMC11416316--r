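## File formats: crosslink CSV, minimal mmCIF bead models, GMM text
## tables, MRC voxel maps (MRC2014 mode 2), YAML configs.

#' Read a crosslink CSV table
#'
#' Dialect: header `protein1,residue1,protein2,residue2,linker`, 1-based
#' residues. Duplicate records (unordered) are collapsed with their
#' multiplicity retained.
#'
#' @param path CSV file path.
#' @return A `crosslink_records` data frame.
#' @export
read_crosslinks <- function(path) {
  if (!file.exists(path)) stop("read_crosslinks: no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein1", "residue1", "protein2", "residue2", "linker")
  if (!all(need %in% names(df)))
    stop("read_crosslinks: header must contain ", paste(need, collapse = ","))
  for (r in seq_len(nrow(df))) {
    for (col in c("residue1", "residue2")) {
      v <- suppressWarnings(as.integer(df[[col]][r]))
      if (is.na(v) || v < 1L)
        stop("read_crosslinks: line ", r + 1L, ": ", col, " = '",
             df[[col]][r], "' is not a positive 1-based residue index")
      df[[col]][r] <- v
    }
    if (!nzchar(df$protein1[r]) || !nzchar(df$protein2[r]))
      stop("read_crosslinks: line ", r + 1L, ": empty protein name")
  }
  df$residue1 <- as.integer(df$residue1)
  df$residue2 <- as.integer(df$residue2)
  a <- paste(df$protein1, df$residue1); b <- paste(df$protein2, df$residue2)
  swap <- a > b
  key <- ifelse(swap, paste(b, a, df$linker), paste(a, b, df$linker))
  mult <- as.integer(table(key)[key])
  out <- df[!duplicated(key), need]
  out$multiplicity <- mult[!duplicated(key)]
  rownames(out) <- NULL
  class(out) <- c("crosslink_records", "data.frame")
  out
}

#' Write a crosslink CSV table
#' @param links `crosslink_records` data frame.
#' @param path Output path.
#' @export
write_crosslinks <- function(links, path) {
  write.csv(links[, c("protein1", "residue1", "protein2", "residue2",
                      "linker")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- mmCIF bead models ---------------------------------------------------

CIF_COLS <- c("group_PDB", "id", "type_symbol", "label_atom_id",
              "label_comp_id", "label_asym_id", "label_seq_id",
              "Cartn_x", "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
              "auth_seq_id", "auth_asym_id")

chain_letter <- function(i) {
  alpha <- LETTERS
  out <- character(length(i))
  for (t in seq_along(i)) {
    n <- i[t] - 1L
    s <- ""
    repeat {
      s <- paste0(alpha[n %% 26L + 1L], s)
      n <- n %/% 26L - 1L
      if (n < 0L) break
    }
    out[t] <- s
  }
  out
}

#' Write a bead model as mmCIF (one pseudo-atom per bead)
#'
#' The bead radius is stored in the B-factor field, the resolution level
#' in the occupancy field, the residue window in
#' `label_seq_id`/`auth_seq_id`, and `subunit:copy` in `auth_asym_id`.
#' With `symmetry = TRUE` all symmetry images are exported.
#'
#' @param state An `assembly_state`.
#' @param path Output path.
#' @param symmetry Export the full rotational assembly.
#' @export
write_model <- function(state, path, symmetry = FALSE) {
  states <- if (symmetry) apply_symmetry(state) else list(state)
  lines <- c("data_npcbasket_model", "#", "loop_",
             paste0("_atom_site.", CIF_COLS))
  id <- 0L
  for (im in seq_along(states)) {
    s <- states[[im]]
    b <- s$bead
    for (i in seq_len(nrow(s$coords))) {
      id <- id + 1L
      lines <- c(lines, sprintf(
        "HETATM %d C CA ALA %s %d %.3f %.3f %.3f %d %.3f %d %s:%d",
        id, chain_letter(b$chain[i] + (im - 1L) * max(b$chain)),
        b$res_first[i], s$coords[i, 1], s$coords[i, 2], s$coords[i, 3],
        b$resolution[i], s$radius[i], b$res_last[i],
        paste0(b$subunit[i]), b$copy[i]))
    }
  }
  writeLines(c(lines, "#"), path)
  invisible(path)
}

#' Read a bead model written by [write_model()]
#'
#' @param path mmCIF path.
#' @return An `assembly_state` (without rigid-body annotation, which the
#'   format does not carry).
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("read_model: no such file: ", path)
  lines <- readLines(path)
  rows <- grep("^HETATM ", lines, value = TRUE)
  if (!length(rows)) stop("read_model: no atom records in ", path)
  f <- do.call(rbind, strsplit(rows, " +"))
  su_cp <- do.call(rbind, strsplit(f[, 14], ":", fixed = TRUE))
  bead <- data.frame(subunit = su_cp[, 1], copy = as.integer(su_cp[, 2]),
                     resolution = as.integer(f[, 11]),
                     res_first = as.integer(f[, 7]),
                     res_last = as.integer(f[, 13]))
  bead$nres <- bead$res_last - bead$res_first + 1L
  coords <- cbind(as.numeric(f[, 8]), as.numeric(f[, 9]),
                  as.numeric(f[, 10]))
  new_assembly_state(coords, as.numeric(f[, 12]), bead)
}

## ---- GMM text tables -----------------------------------------------------

#' Write a Gaussian mixture as a text table
#'
#' One component per line: `weight x y z sigma`. A comment line records
#' the model sigma-scale when present.
#'
#' @param gmm A [gaussian_mixture()].
#' @param path Output path.
#' @export
write_gmm <- function(gmm, path) {
  hdr <- character(0)
  ss <- attr(gmm, "sigma_scale")
  if (!is.null(ss)) hdr <- sprintf("# sigma_scale %.10g", ss)
  body <- sprintf("%.10g %.10g %.10g %.10g %.10g", gmm$weight,
                  gmm$mean[, 1], gmm$mean[, 2], gmm$mean[, 3], gmm$sigma)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a Gaussian mixture text table
#' @param path Path to a `weight x y z sigma` table.
#' @export
read_gmm <- function(path) {
  if (!file.exists(path)) stop("read_gmm: no such file: ", path)
  lines <- readLines(path)
  ss <- NULL
  m <- grep("^# sigma_scale ", lines, value = TRUE)
  if (length(m)) ss <- as.numeric(sub("^# sigma_scale ", "", m[1]))
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- do.call(rbind, lapply(strsplit(lines, " +"), as.numeric))
  g <- gaussian_mixture(f[, 1], f[, 2:4], f[, 5])
  if (!is.null(ss)) attr(g, "sigma_scale") <- ss
  g
}

## ---- MRC voxel maps ------------------------------------------------------

#' Write a voxel map as MRC (mode 2, MRC2014)
#'
#' @param map A `voxel_map` (3D array `data`, `voxel` edge in Angstrom,
#'   `origin` in Angstrom).
#' @param path Output path.
#' @export
write_mrc <- function(map, path) {
  stopifnot(inherits(map, "voxel_map"))
  d <- map$data
  if (!length(d) || all(d == 0)) stop("write_mrc: empty map")
  dims <- dim(d)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(dims)                       # nx ny nz
  wi(2L)                         # mode 2: float32
  wi(c(0L, 0L, 0L))              # nxstart
  wi(dims)                       # mx my mz
  wf(dims * map$voxel)           # cella
  wf(c(90, 90, 90))              # cellb
  wi(c(1L, 2L, 3L))              # mapc mapr maps
  wf(c(min(d), max(d), mean(d))) # dmin dmax dmean
  wi(c(1L, 0L))                  # ispg, nsymbt
  wi(rep(0L, 25L))               # extra
  wf(map$origin)                 # origin x y z (words 50-52)
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst (little-endian)
  wf(stats::sd(d))               # rms
  wi(0L)                         # nlabl
  writeBin(raw(800L), con)       # labels
  wf(as.numeric(d))              # x fastest
  invisible(path)
}

#' Read an MRC voxel map written by [write_mrc()]
#' @param path MRC path.
#' @return A `voxel_map`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("read_mrc: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop("read_mrc: only mode 2 (float32) is supported")
  ri(3)            # nxstart
  ri(3)            # mx
  cella <- rf(3)
  rf(3)            # cellb
  ri(3)            # axis order
  rf(3)            # dmin dmax dmean
  ri(2)            # ispg nsymbt
  ri(25)           # extra
  origin <- rf(3)
  readBin(con, "raw", 8)   # MAP + machst
  rf(1)            # rms
  ri(1)            # nlabl
  readBin(con, "raw", 800)
  d <- rf(prod(dims))
  structure(list(data = array(d, dims), voxel = cella[1] / dims[1],
                 origin = origin),
            class = "voxel_map")
}

## ---- GMM <-> voxel map ---------------------------------------------------

#' Render a Gaussian mixture on a voxel grid
#' @param gmm A [gaussian_mixture()].
#' @param voxel Voxel edge, Angstrom.
#' @param pad Padding beyond the component means, Angstrom.
#' @return A `voxel_map`.
#' @export
gmm_to_map <- function(gmm, voxel = 10, pad = NULL) {
  if (is.null(pad)) pad <- 3 * max(gmm$sigma)
  lo <- apply(gmm$mean, 2, min) - pad
  hi <- apply(gmm$mean, 2, max) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)))
  ax <- lapply(1:3, function(d) lo[d] + (seq_len(dims[d]) - 0.5) * voxel)
  out <- array(0, dims)
  for (c_ in seq_along(gmm$weight)) {
    mu <- gmm$mean[c_, ]; s <- gmm$sigma[c_]
    gx <- exp(-(ax[[1]] - mu[1])^2 / (2 * s^2))
    gy <- exp(-(ax[[2]] - mu[2])^2 / (2 * s^2))
    gz <- exp(-(ax[[3]] - mu[3])^2 / (2 * s^2))
    out <- out + gmm$weight[c_] * (2 * pi * s^2)^(-1.5) *
      outer(outer(gx, gy), gz)
  }
  structure(list(data = out, voxel = voxel, origin = lo),
            class = "voxel_map")
}

#' Fit a Gaussian mixture to a voxel map by expectation-maximization
#'
#' Spherical components with density-weighted voxel centers as data;
#' initialized by k-means on voxels sampled proportionally to density.
#' Deterministic in `seed`.
#'
#' @param map A `voxel_map`.
#' @param K Number of components.
#' @param seed Integer seed.
#' @param n_iter EM iterations.
#' @param min_density Ignore voxels at or below this value.
#' @return A [gaussian_mixture()].
#' @export
fit_gmm_to_map <- function(map, K, seed = 1L, n_iter = 60L,
                           min_density = 0) {
  stopifnot(inherits(map, "voxel_map"), K >= 1L)
  dims <- dim(map$data)
  idx <- which(map$data > min_density, arr.ind = TRUE)
  if (nrow(idx) < K) stop("fit_gmm_to_map: fewer occupied voxels than K")
  X <- sweep((idx - 0.5) * map$voxel, 2, -map$origin)
  w <- map$data[map$data > min_density]
  with_seed(seed, {
    take <- sample.int(nrow(X), min(4000L, nrow(X)), prob = w)
    km <- stats::kmeans(X[take, , drop = FALSE], centers = K, nstart = 3L,
                        iter.max = 50L)
    mu <- km$centers
    # within-cluster spread as the starting width
    s2 <- pmax(km$tot.withinss / max(1, nrow(X[take, , drop = FALSE])) / 3,
               rep(map$voxel^2, K))
    if (length(s2) == 1L) s2 <- rep(s2, K)
    pi_k <- rep(1 / K, K)
    for (it in seq_len(n_iter)) {
      # responsibilities
      logp <- sapply(seq_len(K), function(k2) {
        d2 <- rowSums(sweep(X, 2, mu[k2, ])^2)
        log(pi_k[k2]) - 1.5 * log(2 * pi * s2[k2]) - d2 / (2 * s2[k2])
      })
      mx <- apply(logp, 1, max)
      g <- exp(logp - mx)
      g <- g / rowSums(g)
      wk <- g * w
      Nk <- colSums(wk)
      for (k2 in seq_len(K)) {
        if (Nk[k2] <= 1e-10 * sum(w)) {
          # collapsed component: reseed at the densest voxel
          mu[k2, ] <- X[which.max(w), ]
          s2[k2] <- map$voxel^2
          Nk[k2] <- 1e-10 * sum(w)
          next
        }
        mu[k2, ] <- colSums(X * wk[, k2]) / Nk[k2]
        s2[k2] <- max(sum(wk[, k2] *
                            rowSums(sweep(X, 2, mu[k2, ])^2)) /
                        (3 * Nk[k2]), (map$voxel / 2)^2)
      }
      pi_k <- Nk / sum(Nk)
    }
    gaussian_mixture(pi_k, mu, sqrt(s2))
  })
}

## ---- config and bundle directories --------------------------------------

#' Write a configuration / parameter list as YAML
#' @param config Named list (classed objects are unclassed).
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (!is.null(names(x)) && length(x) > 1L) as.list(x)
    else x
  }
  yaml::write_yaml(strip(config), path, precision = 15L)
  invisible(path)
}

#' Read a YAML configuration
#' @param path YAML path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path)
  yaml::read_yaml(path)
}

#' Write a ground-truth bundle to a directory
#'
#' Writes `crosslinks.csv`, `density_gmm.txt`, `truth.cif` and
#' `params.yaml` (parameters plus simulation settings; the bundle is
#' fully reproducible from `params.yaml` alone).
#'
#' @param bundle A `ground_truth_bundle`.
#' @param dir Output directory (created if missing).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_crosslinks(bundle$crosslinks, file.path(dir, "crosslinks.csv"))
  write_gmm(bundle$density, file.path(dir, "density_gmm.txt"))
  write_model(bundle$truth_state, file.path(dir, "truth.cif"))
  write_config(list(params = bundle$params, settings = bundle$settings),
               file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Rebuild a ground-truth bundle from its directory
#'
#' Regenerates the bundle from the echoed `params.yaml` (bit-identical to
#' the original by seeded determinism).
#'
#' @param dir Directory written by [write_bundle()].
#' @export
read_bundle <- function(dir) {
  cfg <- read_config(file.path(dir, "params.yaml"))
  p <- cfg$params
  params <- ground_truth_params(
    n_symmetry = p$n_symmetry, strut_tilt = p$strut_tilt,
    distal_offset = p$distal_offset,
    distal_ring_diameter = p$distal_ring_diameter,
    strut_thickness = p$strut_thickness,
    scaffold_ring_radius = p$scaffold_ring_radius,
    beads_per_strut = p$beads_per_strut,
    anchor_chain_lengths = unlist(p$anchor_chain_lengths),
    seed = p$seed)
  s <- cfg$settings
  make_ground_truth_bundle(params, xl_cutoff = s$xl_cutoff,
                           n_true = s$n_true, fp_rate = s$fp_rate,
                           sigma_scale = s$sigma_scale, jitter = s$jitter,
                           term_sigma = s$term_sigma)
}
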