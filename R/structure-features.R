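# Structure-derived annotations: inter-residue minimal heavy-atom distances,
# Shrake-Rupley solvent accessibility for the surface filter, and per-residue
# average B-factors for flexibility analysis.

.heavy_atoms <- function(structure) {
  a <- structure$atoms
  a[a$element != "H", , drop = FALSE]
}

.residue_key <- function(chain, resno, icode = "") paste0(chain, ":", resno, icode)

#' Minimal heavy-atom distance between two residues
#'
#' @param structure a \code{structure_model}.
#' @param key_a,key_b residue keys \code{"<chain>:<resno>"} as in
#'   \code{\link{residue_table}}.
#' @return distance in Angstrom.
#' @export
residue_min_distance <- function(structure, key_a, key_b) {
  a <- .heavy_atoms(structure)
  keys <- .residue_key(a$chain, a$resno, a$icode)
  ca <- as.matrix(a[keys == key_a, c("x", "y", "z")])
  cb <- as.matrix(a[keys == key_b, c("x", "y", "z")])
  if (nrow(ca) == 0L) stop("residue has no heavy atoms: ", key_a)
  if (nrow(cb) == 0L) stop("residue has no heavy atoms: ", key_b)
  if (key_a == key_b) return(0)
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * tcrossprod(ca, cb)
  sqrt(max(0, min(d2)))
}

#' All-pairs minimal heavy-atom distance map
#'
#' @param structure a \code{structure_model}.
#' @param keys residue keys to include (default all residues).
#' @return symmetric matrix of distances (Angstrom) with key dimnames.
#' @export
distance_map <- function(structure, keys = NULL) {
  a <- .heavy_atoms(structure)
  akeys <- .residue_key(a$chain, a$resno, a$icode)
  if (is.null(keys)) keys <- unique(akeys)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  idx <- split(seq_len(nrow(a)), factor(akeys, levels = keys))
  if (any(lengths(idx) == 0L))
    stop("residue has no heavy atoms: ",
         paste(keys[lengths(idx) == 0L], collapse = ", "))
  n <- length(keys)
  out <- matrix(0, n, n, dimnames = list(keys, keys))
  sq <- rowSums(xyz^2)
  for (i in seq_len(n - 1L)) {
    ia <- idx[[i]]
    for (j in seq(i + 1L, n)) {
      ib <- idx[[j]]
      d2 <- outer(sq[ia], sq[ib], "+") - 2 * tcrossprod(xyz[ia, , drop = FALSE],
                                                        xyz[ib, , drop = FALSE])
      out[i, j] <- out[j, i] <- sqrt(max(0, min(d2)))
    }
  }
  out
}

# deterministic near-uniform points on the unit sphere (golden-spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.atom_radii <- function(elements) {
  r <- VDW_RADII[elements]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element radius for: ",
            paste(unique(elements[unknown]), collapse = ", "),
            "; using ", VDW_DEFAULT_RADIUS, " A")
    r[unknown] <- VDW_DEFAULT_RADIUS
  }
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Sphere sampling with a deterministic golden-spiral point set over heavy
#' atoms; residue SASA is the sum over its atoms, and relative SASA divides
#' by the theoretical per-residue-type maximum.
#'
#' @param structure a \code{structure_model}.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sample points per atom sphere (default 960).
#' @return data frame with one row per residue: key, chain, resno, aa,
#'   sasa (A^2), rel_sasa.
#' @export
shrake_rupley_sasa <- function(structure, probe = 1.4, n_points = 960) {
  a <- .heavy_atoms(structure)
  if (nrow(a) == 0L) stop("structure has no heavy atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- .atom_radii(a$element) + probe
  pts <- .sphere_points(n_points)
  n_atoms <- nrow(a)
  atom_sasa <- numeric(n_atoms)
  # neighbour prefilter: atoms whose spheres can intersect
  max_r <- max(radii)
  for (i in seq_len(n_atoms)) {
    ri <- radii[i]
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d < ri + max_r & seq_len(n_atoms) != i)
    nb <- nb[d[nb] < ri + radii[nb]]
    surf <- pts * ri + rep(xyz[i, ], each = n_points)
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
          (surf[, 3] - xyz[j, 3])^2
        free <- free & dj2 > radii[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else {
      frac <- 1
    }
    atom_sasa[i] <- frac * 4 * pi * ri^2
  }
  key <- .residue_key(a$chain, a$resno, a$icode)
  per_res <- tapply(atom_sasa, factor(key, levels = unique(key)), sum)
  rt <- residue_table(structure)
  rt <- rt[match(names(per_res), rt$key), , drop = FALSE]
  rel <- as.numeric(per_res) / unname(MAX_SASA[rt$aa])
  data.frame(key = rt$key, chain = rt$chain, resno = rt$resno, aa = rt$aa,
             sasa = as.numeric(per_res), rel_sasa = rel,
             stringsAsFactors = FALSE)
}

#' Surface residues by relative accessibility
#'
#' @param sasa data frame from \code{\link{shrake_rupley_sasa}}.
#' @param rel_threshold relative-SASA cutoff, inclusive (default 0.25).
#' @return character vector of surface residue keys.
#' @export
surface_mask <- function(sasa, rel_threshold = 0.25) {
  sasa$key[sasa$rel_sasa >= rel_threshold]
}

#' Per-residue average B-factors and flexibility ranking
#'
#' @param structure a \code{structure_model} with B-factors.
#' @return data frame with one row per residue: key, chain, resno, aa,
#'   mean_b, z (z-score across residues), rank (1 = most flexible).
#' @export
residue_avg_bfactor <- function(structure) {
  a <- structure$atoms
  key <- .residue_key(a$chain, a$resno, a$icode)
  fkey <- factor(key, levels = unique(key))
  mean_b <- tapply(a$b, fkey, function(b) mean(b, na.rm = TRUE))
  mean_b[is.nan(mean_b)] <- NA_real_
  rt <- residue_table(structure)
  rt <- rt[match(names(mean_b), rt$key), , drop = FALSE]
  mb <- as.numeric(mean_b)
  if (all(is.na(mb)) || all(mb[!is.na(mb)] == 0)) {
    warning("all B-factors missing or zero; flexibility ranking is ",
            "residue order")
    z <- rep(0, length(mb))
    rank_ <- seq_along(mb)
  } else {
    mu <- mean(mb, na.rm = TRUE)
    sdv <- stats::sd(mb, na.rm = TRUE)
    z <- if (is.na(sdv) || sdv == 0) rep(0, length(mb)) else (mb - mu) / sdv
    # most flexible first; ties broken by lower residue number
    ord <- order(-ifelse(is.na(mb), -Inf, mb), rt$resno)
    rank_ <- integer(length(mb))
    rank_[ord] <- seq_along(ord)
  }
  data.frame(key = rt$key, chain = rt$chain, resno = rt$resno, aa = rt$aa,
             mean_b = mb, z = z, rank = rank_, stringsAsFactors = FALSE)
}

#' Most flexible residues by average B-factor
#'
#' @param track data frame from \code{\link{residue_avg_bfactor}}.
#' @param top_n number of residues to propose as saturation targets.
#' @return data frame of the selected residues, most flexible first.
#' @export
flexible_positions <- function(track, top_n) {
  stopifnot(top_n >= 1)
  if (top_n > nrow(track)) {
    warning("top_n exceeds residue count; returning all residues")
    top_n <- nrow(track)
  }
  sel <- track[order(track$rank), , drop = FALSE]
  utils::head(sel, top_n)
}
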