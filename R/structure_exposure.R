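# van der Waals radii (Angstrom) used for SASA and projection
.VDW <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)
.VDW_DEFAULT <- 1.7

#' Maximal residue solvent accessibility reference
#'
#' Theoretical maximum solvent accessible surface area (Angstrom^2) of each
#' residue type in an extended Gly-X-Gly tripeptide (Tien et al. 2013),
#' used by [relative_sasa()] to normalise per-residue areas.
#'
#' @format named numeric vector over the 20 amino acids.
#' @export
MAX_SASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174)

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Parse a PDB structure file
#'
#' Minimal fixed-column reader for ATOM/HETATM records; multi-model files
#' contribute only their first model. Element radii are assigned from the
#' element column (falling back to the first letter of the atom name);
#' unknown elements get the default carbon radius with a warning. Hydrogens
#' are dropped.
#'
#' @param path PDB file.
#' @return a `structure_model` data.table: `atom`, `element`, `resname`,
#'   `chain`, `resno`, `x`, `y`, `z`, `radius`.
#' @export
parse_structure <- function(path) {
  lines <- readLines(path)
  end1 <- which(startsWith(lines, "ENDMDL"))
  if (length(end1)) lines <- lines[seq_len(end1[1] - 1)]
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) stop("no ATOM records in ", path, call. = FALSE)
  fld <- function(a, b) trimws(substr(rec, a, b))
  el <- fld(77, 78)
  name <- fld(13, 16)
  el[el == ""] <- substr(gsub("[0-9]", "", name[el == ""]), 1, 1)
  el <- toupper(el)
  keep <- el != "H"
  dt <- data.table(
    atom = name[keep], element = el[keep], resname = fld(18, 20)[keep],
    chain = fld(22, 22)[keep], resno = as.integer(fld(23, 26))[keep],
    x = as.numeric(fld(31, 38))[keep], y = as.numeric(fld(39, 46))[keep],
    z = as.numeric(fld(47, 54))[keep])
  if (any(!is.finite(dt$x + dt$y + dt$z)))
    stop("non-finite coordinates in ", path, call. = FALSE)
  unknown <- setdiff(unique(dt$element), names(.VDW))
  if (length(unknown))
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; default radius ", .VDW_DEFAULT, " applied")
  dt[, radius := ifelse(element %in% names(.VDW), .VDW[element],
                        .VDW_DEFAULT)]
  structure(dt, class = c("structure_model", class(dt)), source = path)
}

# quasi-uniform points on the unit sphere (golden-spiral lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Per atom, the fraction of quasi-uniform test points on the expanded
#' sphere of radius `radius + probe` not inside any neighbour's expanded
#' sphere, times `4 pi (radius + probe)^2`.
#'
#' @param structure a `structure_model`.
#' @param probe probe radius (default 1.4, water).
#' @param n_points test points per atom (>= 100; default 960).
#' @return list with `atom_area` (per atom, Angstrom^2) and
#'   `residue_area` (data.table by chain/resno/resname).
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960) {
  stopifnot(n_points >= 100)
  pts <- .sphere_points(n_points)
  xyz <- as.matrix(structure[, .(x, y, z)])
  r <- structure$radius + probe
  n <- nrow(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    p <- pts * r[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      d2j <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & d2j >= r[j]^2
      if (!any(free)) break
    }
    area[i] <- sum(free) / n_points * 4 * pi * r[i]^2
  }
  res <- data.table(chain = structure$chain, resno = structure$resno,
                    resname = structure$resname, area = area)
  list(atom_area = area,
       residue_area = res[, .(area = sum(area)),
                          by = .(chain, resno, resname)])
}

#' Relative solvent accessibility
#'
#' Residue SASA divided by its maximal extended-state reference area;
#' residues at or above `cut` are classified exposed.
#'
#' @param area per-residue area(s), Angstrom^2.
#' @param restype one- or three-letter residue type(s).
#' @param cut exposure threshold (default 0.40, inclusive).
#' @return data.table `rel_sasa`, `exposed`.
#' @export
relative_sasa <- function(area, restype, cut = 0.40) {
  key <- ifelse(nchar(restype) == 3, .AA3TO1[toupper(restype)], restype)
  if (any(is.na(key)) || !all(key %in% names(MAX_SASA)))
    stop("unknown residue type(s): ",
         paste(unique(restype[is.na(key) | !key %in% names(MAX_SASA)]),
               collapse = ", "), call. = FALSE)
  rel <- area / MAX_SASA[key]
  data.table(rel_sasa = unname(rel), exposed = unname(rel) >= cut)
}

#' Truncate diversified residues to alanine
#'
#' Removes side-chain atoms beyond the beta carbon at the listed residue
#' numbers, removing wild-type residue size bias before the orientation
#' search. Glycines (no CB) are left untouched.
#'
#' @param structure a `structure_model`.
#' @param resnos residue numbers to truncate.
#' @return a truncated `structure_model`.
#' @export
ala_truncate <- function(structure, resnos) {
  stopifnot(all(resnos %in% structure$resno))
  keep_atoms <- c("N", "CA", "C", "O", "CB", "OXT")
  out <- structure[!(structure$resno %in% resnos) |
                     structure$atom %in% keep_atoms]
  for (a in c("class", "source")) attr(out, a) <- attr(structure, a)
  out
}

# z-buffer projected visible area of selected spheres along view dir v.
# Returns named vector: per target atom index, visible area (Angstrom^2).
.projected_visible <- function(xyz, radius, targets, v, grid = 0.25) {
  v <- v / sqrt(sum(v^2))
  up <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- up - sum(up * v) * v
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  px <- xyz %*% e1
  py <- xyz %*% e2
  pz <- xyz %*% v
  x0 <- min(px - radius); x1 <- max(px + radius)
  y0 <- min(py - radius); y1 <- max(py + radius)
  gx <- seq(x0 + grid / 2, x1, by = grid)
  gy <- seq(y0 + grid / 2, y1, by = grid)
  best <- matrix(-Inf, length(gx), length(gy))
  owner <- matrix(0L, length(gx), length(gy))
  for (i in seq_len(nrow(xyz))) {
    ix <- which(abs(gx - px[i]) <= radius[i])
    iy <- which(abs(gy - py[i]) <= radius[i])
    if (!length(ix) || !length(iy)) next
    dx2 <- (gx[ix] - px[i])^2
    dy2 <- (gy[iy] - py[i])^2
    d2 <- outer(dx2, dy2, "+")
    inside <- d2 < radius[i]^2
    if (!any(inside)) next
    h <- matrix(-Inf, length(ix), length(iy))
    h[inside] <- pz[i] + sqrt(radius[i]^2 - d2[inside])
    sub_best <- best[ix, iy, drop = FALSE]
    upd <- h > sub_best
    sub_best[upd] <- h[upd]
    best[ix, iy] <- sub_best
    sub_owner <- owner[ix, iy, drop = FALSE]
    sub_owner[upd] <- i
    owner[ix, iy] <- sub_owner
  }
  vis <- tabulate(owner[owner > 0], nbins = nrow(xyz))[targets] * grid^2
  setNames(vis, targets)
}

# spherical grid of viewing directions
.view_grid <- function(theta, phi) {
  g <- expand.grid(theta = theta, phi = phi)
  cbind(sin(g$theta) * cos(g$phi), sin(g$theta) * sin(g$phi),
        cos(g$theta), g$theta, g$phi)
}

#' Orientation search for target-interface accessibility
#'
#' Finds the viewing orientations that maximise the total visible
#' projected area of the diversified side chains (represented as single
#' spheres at the beta carbon of the alanine-truncated structure, occluded
#' by all atoms under an orthographic z-buffer), then reports per site the
#' maximum visible area over the optimal orientation set - all
#' orientations within `tol` (default 5\%) of the best total.
#'
#' @param structure an ala-truncated `structure_model`
#'   (see [ala_truncate()]).
#' @param resnos diversified residue numbers (must have CB atoms unless
#'   glycine, which is represented at CA).
#' @param coarse_step,fine_step angular steps in degrees for the coarse
#'   and fine searches.
#' @param tol inclusion tolerance for near-optimal orientations.
#' @param grid raster resolution in Angstrom.
#' @return named numeric vector: residue number -> maximum visible
#'   side-chain area (Angstrom^2) over the optimal orientation set.
#' @export
orientation_accessibility <- function(structure, resnos, coarse_step = 10,
                                      fine_step = 1, tol = 0.05,
                                      grid = 0.25) {
  if (!length(resnos)) stop("no diversified sites", call. = FALSE)
  xyz <- as.matrix(structure[, .(x, y, z)])
  radius <- structure$radius
  targets <- vapply(resnos, function(rn) {
    i <- which(structure$resno == rn & structure$atom == "CB")
    if (!length(i)) i <- which(structure$resno == rn &
                                 structure$atom == "CA")
    if (!length(i)) stop("site ", rn, " absent from structure",
                         call. = FALSE)
    i[1]
  }, integer(1))
  eval_dirs <- function(dirs) {
    out <- matrix(0, nrow(dirs), length(targets))
    for (r in seq_len(nrow(dirs)))
      out[r, ] <- .projected_visible(xyz, radius, targets, dirs[r, 1:3],
                                     grid)
    out
  }
  rad <- pi / 180
  coarse <- .view_grid(seq(0, 180, by = coarse_step) * rad,
                       seq(0, 360 - coarse_step, by = coarse_step) * rad)
  vis_c <- eval_dirs(coarse)
  tot_c <- rowSums(vis_c)
  bi <- which.max(tot_c)
  th0 <- coarse[bi, 4]; ph0 <- coarse[bi, 5]
  fine <- .view_grid(
    pmin(pi, pmax(0, th0 + seq(-coarse_step, coarse_step,
                               by = fine_step) * rad)),
    ph0 + seq(-coarse_step, coarse_step, by = fine_step) * rad)
  vis_f <- eval_dirs(fine)
  vis <- rbind(vis_c, vis_f)
  tot <- c(tot_c, rowSums(vis_f))
  near <- tot >= (1 - tol) * max(tot)
  out <- apply(vis[near, , drop = FALSE], 2, max)
  setNames(out, resnos)
}

#' Per-site exposure scores
#'
#' Combines, per diversified site and averaged over structures, the
#' relative solvent accessibility of the full residue with the normalised
#' orientation-search accessibility of its alanine-truncated side chain;
#' the exposure score is the product, rescaled to `[0, 1]` by the maximum
#' across sites.
#'
#' @param structures list of `structure_model`s (crystal structures of the
#'   same scaffold).
#' @param resnos diversified residue numbers, present in every structure.
#' @param site_labels optional labels for the output (default the residue
#'   numbers).
#' @param probe,n_points passed to [sasa()].
#' @param ... passed to [orientation_accessibility()].
#' @return an `exposure_profile` data.table: `site`, `rel_sasa`,
#'   `accessibility` (Angstrom^2), `eps` in `[0, 1]`.
#' @export
exposure_score <- function(structures, resnos, site_labels = NULL,
                           probe = 1.4, n_points = 960, ...) {
  stopifnot(length(structures) >= 1)
  rel <- matrix(NA_real_, length(structures), length(resnos))
  acc <- matrix(NA_real_, length(structures), length(resnos))
  for (si in seq_along(structures)) {
    st <- structures[[si]]
    if (!all(resnos %in% st$resno))
      stop("site(s) absent from structure ", si, call. = FALSE)
    sa <- sasa(st, probe, n_points)$residue_area
    tr <- ala_truncate(st, resnos)
    oa <- orientation_accessibility(tr, resnos, ...)
    for (j in seq_along(resnos)) {
      row <- sa[sa$resno == resnos[j]][1]
      rel[si, j] <- relative_sasa(row$area, row$resname)$rel_sasa
      acc[si, j] <- oa[[as.character(resnos[j])]]
    }
  }
  rel_m <- colMeans(rel)
  acc_m <- colMeans(acc)
  eps <- rel_m * acc_m
  if (max(eps) > 0) eps <- eps / max(eps)
  structure(data.table(
    site = if (is.null(site_labels)) as.character(resnos) else site_labels,
    rel_sasa = rel_m, accessibility = acc_m, eps = eps),
    class = c("exposure_profile", "data.table", "data.frame"))
}
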