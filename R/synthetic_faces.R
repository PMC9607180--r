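# Synthetic paired facial meshes with known ground truth.
#
# The face is a parametric height field over an ellipsoidal base: smooth
# Gaussian bumps (nose, lips, chin, brow, cheekbones) and depressions
# (orbital sockets, temporal fossae, nasolabial and mentolabial grooves).
# It is not anatomically realistic; what matters for validating the
# pipeline is that every named facial region exists with a controllable
# convexity class, because scan error is modelled as concavity-dependent.

#' Parameters of the synthetic face
#'
#' Sizes and feature amplitudes in mm. `eyelid` controls the depth of the
#' orbital depression: closed lids (typical for CBCT, where patients relax
#' the eyes) partially fill the socket, open lids deepen it by
#' `eyelid_extra`.
#'
#' @param width,height,depth overall head-size scalars (mm).
#' @param nose,lips,chin,brow,eye_socket feature amplitudes (mm);
#'   `eye_socket` is the depth of the orbital depression.
#' @param eyelid `"closed"` or `"open"`.
#' @param eyelid_extra additional socket depth when eyelids are open (mm).
#' @param resolution grid vertices per axis (>= 30).
#' @param seed stored for bookkeeping; generation itself is deterministic.
#' @return object of class `face_params`.
#' @export
face_params <- function(width = 140, height = 180, depth = 60,
                        nose = 12, lips = 4, chin = 6, brow = 3,
                        eye_socket = 4, eyelid = c("closed", "open"),
                        eyelid_extra = 2, resolution = 140, seed = 1L) {
  eyelid <- match.arg(eyelid)
  amps <- c(width = width, height = height, depth = depth, nose = nose,
            lips = lips, chin = chin, brow = brow, eye_socket = eye_socket,
            eyelid_extra = eyelid_extra)
  if (any(!is.finite(amps))) stop("all size/amplitude parameters must be finite")
  if (resolution < 30) stop("resolution must be at least 30 vertices per axis")
  structure(list(width = width, height = height, depth = depth, nose = nose,
                 lips = lips, chin = chin, brow = brow,
                 eye_socket = eye_socket, eyelid = eyelid,
                 eyelid_extra = eyelid_extra,
                 resolution = as.integer(resolution), seed = as.integer(seed)),
            class = "face_params")
}

# Gaussian feature table for a parameter set. Columns: x0, y0, sx, sy, amp.
face_features <- function(p) {
  socket <- p$eye_socket + if (p$eyelid == "open") p$eyelid_extra else 0
  f <- rbind(
    c(0, 5, 7, 16, p$nose),          # nasal ridge / apex
    c(-12, -3, 4, 4, 0.25 * p$nose), # alae
    c(12, -3, 4, 4, 0.25 * p$nose),
    c(-20, 36, 12, 5, p$brow),       # brow ridges
    c(20, 36, 12, 5, p$brow),
    c(0, 38, 8, 6, 0.7 * p$brow),    # glabella
    c(-27, 27, 9, 5.5, -socket),     # orbital sockets (concave)
    c(27, 27, 9, 5.5, -socket),
    c(0, -25, 14, 8, p$lips),        # lips
    c(0, -37, 12, 3, -1.5),          # oral fissure groove
    c(0, -46, 11, 4, -3),            # mentolabial sulcus (concave)
    c(0, -58, 12, 8, p$chin),        # chin
    c(-42, 12, 9, 7, 3.5),           # zygomatic prominences
    c(42, 12, 9, 7, 3.5),
    c(-50, 38, 9, 9, -2.5),          # temporal fossae (concave)
    c(50, 38, 9, 9, -2.5),
    c(-20, -10, 4.5, 6, -2),         # nasolabial grooves
    c(20, -10, 4.5, 6, -2),
    c(-36, -18, 8, 7, -1.5),         # buccal hollows
    c(36, -18, 8, 7, -1.5))
  colnames(f) <- c("x0", "y0", "sx", "sy", "amp")
  f
}

# Height of the face surface at (x, y); vectorized.
face_height <- function(x, y, p) {
  a <- p$width / 2
  b <- p$height / 2
  z <- p$depth * sqrt(pmax(0, 1 - (x / a)^2 - (y / b)^2))
  for (i in seq_len(nrow(ft <- face_features(p)))) {
    z <- z + ft[i, "amp"] *
      exp(-((x - ft[i, "x0"])^2 / (2 * ft[i, "sx"]^2) +
            (y - ft[i, "y0"])^2 / (2 * ft[i, "sy"]^2)))
  }
  z
}

# Facial-region atlas layout: centres and semi-axes (mm) of elliptical
# patches in the (x, y) parameter plane. Regions with two patches (e.g.
# temporal) carry the same name twice. L = negative x, R = positive x.
facial_region_layout <- function() {
  single <- rbind(
    c("apex of nose", 0, 2, 9, 5),
    c("philtrum", 0, -13, 12, 4.5),
    c("vermilion border", 0, -21, 12, 4.5),
    c("vermilion", 0, -29, 12, 4.5),
    c("oral fissure", 0, -37, 12, 4.5),
    c("sulcus mentolabialis", 0, -46, 11, 4.5),
    c("mental region", 0, -58, 13, 7),
    c("frontal region", 0, 60, 45, 18))
  lr <- rbind(
    c("ala nasi", 13, -2, 6.5, 5.5),
    c("nasal bridge", 7, 18, 5.5, 6.5),
    c("sulcus nasolabialis", 20, -10, 6, 6.5),
    c("oral/labial commissure", 25, -33, 6.5, 5.5),
    c("orbital region", 27, 27, 10, 6))
  both <- rbind(
    c("temporal region", 50, 38, 10, 10),
    c("zygomatic region", 42, 12, 9, 7),
    c("infraorbital region", 17, 8, 8, 5.5),
    c("parotid-masseteric region", 50, -32, 10, 10),
    c("buccal region", 36, -18, 8, 7))
  rows <- list()
  add <- function(nm, x, y, rx, ry) rows[[length(rows) + 1]] <<- list(
    region = nm, x = as.numeric(x), y = as.numeric(y),
    rx = as.numeric(rx), ry = as.numeric(ry))
  for (i in seq_len(nrow(single)))
    add(single[i, 1], single[i, 2], single[i, 3], single[i, 4], single[i, 5])
  for (i in seq_len(nrow(lr))) {
    add(paste(lr[i, 1], "L"), -as.numeric(lr[i, 2]), lr[i, 3], lr[i, 4], lr[i, 5])
    add(paste(lr[i, 1], "R"), as.numeric(lr[i, 2]), lr[i, 3], lr[i, 4], lr[i, 5])
  }
  for (i in seq_len(nrow(both))) {
    add(both[i, 1], -as.numeric(both[i, 2]), both[i, 3], both[i, 4], both[i, 5])
    add(both[i, 1], as.numeric(both[i, 2]), both[i, 3], both[i, 4], both[i, 5])
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Names of the facial regions in the atlas
#'
#' The 23 named facial locations evaluated by the pipeline. Note that both
#' "vermilion border" and "vermilion" appear: the source clinical table
#' lists both even while describing 21 locations; the atlas carries all 23
#' and surfaces the discrepancy rather than resolving it.
#' @return character vector of 23 region names.
#' @export
atlas_region_names <- function() unique(facial_region_layout()$region)

#' Generate a synthetic facial surface with landmarks and region atlas
#'
#' Builds a triangulated open facial shell (height field over an
#' ellipsoidal base), six expression-stable landmarks (glabella, left and
#' right temple, pronasale, left and right zygion) and a vertex-to-region
#' atlas covering the 23 named facial locations. Generation is fully
#' deterministic in the parameters.
#'
#' @param params a [face_params()] object.
#' @param min_region_vertices minimum shell vertices a region must contain;
#'   the default 20 matches the assessability rule downstream. Lower it for
#'   deliberately coarse test meshes.
#' @return object of class `synthetic_face`: list with `mesh`
#'   (`triangle_mesh`), `landmarks` (6 x 3 named matrix), `atlas`
#'   (character per vertex, `NA` when unassigned), `concavity` (per-vertex
#'   positive-part Laplacian of the height field, normalized to `[0, 1]`)
#'   and `params`.
#' @export
generate_face <- function(params = face_params(), min_region_vertices = 20) {
  stopifnot(inherits(params, "face_params"))
  n <- params$resolution
  a <- params$width / 2
  b <- params$height / 2
  xs <- seq(-a, a, length.out = n)
  ys <- seq(-b, b, length.out = n)
  g <- expand.grid(x = xs, y = ys)  # x varies fastest
  e <- (g$x / a)^2 + (g$y / b)^2
  keep <- e <= 0.94  # stay off the near-vertical ellipsoid rim
  z <- face_height(g$x, g$y, params)

  # vertex indexing on the kept grid
  idx <- matrix(NA_integer_, n, n)  # [i (x), j (y)]
  idx[cbind(rep(seq_len(n), n), rep(seq_len(n), each = n))[keep, ]] <-
    seq_len(sum(keep))
  verts <- cbind(g$x[keep], g$y[keep], z[keep])

  # two triangles per fully-kept cell, counter-clockwise seen from +z
  i <- rep(seq_len(n - 1), n - 1)
  j <- rep(seq_len(n - 1), each = n - 1)
  v00 <- idx[cbind(i, j)]; v10 <- idx[cbind(i + 1, j)]
  v01 <- idx[cbind(i, j + 1)]; v11 <- idx[cbind(i + 1, j + 1)]
  ok <- !is.na(v00) & !is.na(v10) & !is.na(v01) & !is.na(v11)
  faces <- rbind(cbind(v00[ok], v10[ok], v11[ok]),
                 cbind(v00[ok], v11[ok], v01[ok]))
  mesh <- triangle_mesh(verts, faces)

  # concavity: positive part of the grid Laplacian of z, normalized
  zm <- matrix(z, n, n)
  dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
  lap <- matrix(0, n, n)
  lap[2:(n - 1), ] <- lap[2:(n - 1), ] +
    (zm[1:(n - 2), ] + zm[3:n, ] - 2 * zm[2:(n - 1), ]) / dx^2
  lap[, 2:(n - 1)] <- lap[, 2:(n - 1)] +
    (zm[, 1:(n - 2)] + zm[, 3:n] - 2 * zm[, 2:(n - 1)]) / dy^2
  conc <- pmax(0, as.vector(lap))[keep]
  if (max(conc) > 0) conc <- conc / max(conc)

  # atlas: nearest region centre in normalized elliptical distance, <= 1
  lay <- facial_region_layout()
  nd <- matrix(Inf, nrow(verts), nrow(lay))
  for (r in seq_len(nrow(lay)))
    nd[, r] <- ((verts[, 1] - lay$x[r]) / lay$rx[r])^2 +
               ((verts[, 2] - lay$y[r]) / lay$ry[r])^2
  best <- max.col(-nd)
  atlas <- ifelse(nd[cbind(seq_len(nrow(verts)), best)] <= 1,
                  lay$region[best], NA_character_)

  counts <- table(atlas)
  missing <- setdiff(atlas_region_names(), names(counts))
  small <- names(counts)[counts < min_region_vertices]
  if (length(missing) > 0 || length(small) > 0)
    stop(sprintf(
      "resolution %d too low to host all regions with >= %d vertices (offenders: %s)",
      n, min_region_vertices, paste(c(missing, small), collapse = ", ")))

  lm <- rbind(glabella = c(0, 38), temple_L = c(-50, 38), temple_R = c(50, 38),
              pronasale = c(0, 2), zygion_L = c(-42, 12), zygion_R = c(42, 12))
  landmarks <- cbind(lm, face_height(lm[, 1], lm[, 2], params))
  colnames(landmarks) <- c("x", "y", "z")

  structure(list(mesh = mesh, landmarks = landmarks, atlas = atlas,
                 concavity = conc, params = params),
            class = "synthetic_face")
}

#' Perturbation recipe for deriving a scan from a reference face
#'
#' Describes everything that separates the depth-sensor scan from the
#' reference shell: per-region surface offsets (the injected "true"
#' deviations, mm, applied along vertex normals), depth noise whose
#' standard deviation grows with local concavity (smartphone depth sensors
#' degrade in concave structures), a known rigid misalignment, and the two
#' reference-shell artifacts seen in practice (cropped upper forehead,
#' eyelid state mismatch).
#'
#' @param offsets named numeric vector, region name -> offset amplitude
#'   (mm, >= 0). Regions not named get 0.
#' @param noise_sd base depth-noise standard deviation (mm). Default
#'   0.15 mm; concavity scales it up to `noise_sd + concavity_gain`.
#' @param concavity_gain extra noise sd (mm) at maximum concavity.
#' @param misalign_angles,misalign_trans rigid misalignment of the scan
#'   (degrees about x,y,z; translation mm).
#' @param forehead_crop fraction in `[0, 1)` of the frontal region's height
#'   span removed from the TOP of the reference shell.
#' @param eyelid_mismatch if TRUE, adds `eyelid_offset` mm to both orbital
#'   regions (open eyes on the scan vs closed on the reference shell).
#' @param eyelid_offset orbital offset used for the eyelid mismatch (mm).
#' @param resolution_ratio scan grid resolution per axis relative to the
#'   shell (default 0.5, i.e. ~25% of the face count).
#' @return object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(offsets = numeric(0), noise_sd = 0.15,
                              concavity_gain = 0.3,
                              misalign_angles = c(0, 0, 0),
                              misalign_trans = c(0, 0, 0),
                              forehead_crop = 0, eyelid_mismatch = FALSE,
                              eyelid_offset = 4, resolution_ratio = 0.5) {
  if (length(offsets) > 0 && (is.null(names(offsets)) || any(offsets < 0)))
    stop("'offsets' must be a named vector of nonnegative amplitudes")
  bad <- setdiff(names(offsets), atlas_region_names())
  if (length(bad) > 0)
    stop("unknown region(s) in offsets: ", paste(bad, collapse = ", "))
  if (forehead_crop < 0 || forehead_crop >= 1)
    stop("forehead_crop must lie in [0, 1)")
  if (noise_sd < 0 || concavity_gain < 0) stop("noise parameters must be >= 0")
  structure(list(offsets = offsets, noise_sd = noise_sd,
                 concavity_gain = concavity_gain,
                 misalign_angles = misalign_angles,
                 misalign_trans = misalign_trans,
                 forehead_crop = forehead_crop,
                 eyelid_mismatch = eyelid_mismatch,
                 eyelid_offset = eyelid_offset,
                 resolution_ratio = resolution_ratio),
            class = "perturbation_spec")
}

#' Derive a reference-shell / scan pair with known ground truth
#'
#' The reference shell is the full-resolution face (optionally cropped at
#' the top of the forehead). The scan is the same parametric surface
#' sampled at `resolution_ratio` per axis (~25% of the faces by default),
#' with per-region normal-direction offsets, concavity-dependent depth
#' noise, and the specified rigid misalignment applied. The returned ground
#' truth records the exact per-region offsets and the misalignment.
#'
#' @param face a [generate_face()] result.
#' @param spec a [perturbation_spec()].
#' @param seed RNG seed for the depth noise (the only stochastic part).
#' @return object of class `face_pair`: `shell`, `shell_atlas`, `scan`,
#'   `scan_atlas`, `shell_landmarks`, `scan_landmarks` (misaligned), and
#'   `truth` (list with `region_dev` — named per-region true deviation in
#'   mm over all 23 regions —, `transform`, `artifacts`).
#' @export
derive_pair <- function(face, spec = perturbation_spec(), seed = 1L) {
  stopifnot(inherits(face, "synthetic_face"), inherits(spec, "perturbation_spec"))
  regions <- atlas_region_names()
  off <- structure(numeric(length(regions)), names = regions)
  off[names(spec$offsets)] <- spec$offsets
  if (spec$eyelid_mismatch) {
    off["orbital region L"] <- off["orbital region L"] + spec$eyelid_offset
    off["orbital region R"] <- off["orbital region R"] + spec$eyelid_offset
  }
  if (any(off > 10))
    stop("offset(s) above 10 mm would self-intersect the facial surface")

  # reference shell (+ optional forehead crop)
  shell <- face$mesh
  shell_atlas <- face$atlas
  if (spec$forehead_crop > 0) {
    fy <- shell$vertices[!is.na(shell_atlas) & shell_atlas == "frontal region", 2]
    thr <- min(fy) + (1 - spec$forehead_crop) * diff(range(fy))
    keep <- shell$vertices[, 2] <= thr
    remap <- cumsum(keep)
    fkeep <- keep[shell$faces[, 1]] & keep[shell$faces[, 2]] & keep[shell$faces[, 3]]
    shell <- triangle_mesh(shell$vertices[keep, , drop = FALSE],
                           matrix(remap[shell$faces[fkeep, ]], ncol = 3))
    shell_atlas <- shell_atlas[keep]
  }

  # scan: resample the same parametric surface at reduced resolution
  sp <- face$params
  sp$resolution <- max(30L, as.integer(round(sp$resolution * spec$resolution_ratio)))
  sface <- generate_face(sp, min_region_vertices = 1)
  scan <- sface$mesh
  nrm <- vertex_normals(scan)
  vdev <- ifelse(is.na(sface$atlas), 0, off[sface$atlas])
  disp <- with_seed(seed, {
    sd_i <- spec$noise_sd + spec$concavity_gain * sface$concavity
    vdev + rnorm(nrow(scan$vertices), 0, sd_i)
  })
  scan$vertices <- scan$vertices + nrm * disp

  mis <- rt_from_angles(spec$misalign_angles, spec$misalign_trans)
  scan <- rt_apply(mis, scan)
  scan_landmarks <- rt_apply(mis, sface$landmarks)
  rownames(scan_landmarks) <- rownames(sface$landmarks)

  structure(list(
    shell = shell, shell_atlas = shell_atlas,
    scan = scan, scan_atlas = sface$atlas,
    shell_landmarks = face$landmarks, scan_landmarks = scan_landmarks,
    truth = list(region_dev = off, transform = mis,
                 artifacts = list(forehead_crop = spec$forehead_crop,
                                  eyelid_mismatch = spec$eyelid_mismatch)),
    spec = spec), class = "face_pair")
}

#' Per-region deviation profile for cohort simulation
#'
#' Gives each region a per-sex Bernoulli probability of carrying a
#' clinically relevant (> 3 mm) defect. Defect amplitudes are drawn from
#' `defect_range` (>= 4 mm so the flag is unambiguous), all other regions
#' from `null_range` (<= 1 mm).
#'
#' @param rates data.frame with columns `region`, `p_men`, `p_women`.
#' @param defect_range,null_range amplitude ranges (mm) for defect /
#'   non-defect regions.
#' @param misalign_max_deg,misalign_max_mm per-subject misalignment is drawn
#'   uniformly within these bounds per axis.
#' @param crop_prob,crop_fraction probability and size of the forehead-crop
#'   artifact on the reference shell.
#' @param noise_sd,concavity_gain depth-noise model passed through to
#'   [perturbation_spec()].
#' @return object of class `deviation_profile`.
#' @export
deviation_profile <- function(rates, defect_range = c(4, 8),
                              null_range = c(0, 1),
                              misalign_max_deg = 5, misalign_max_mm = 5,
                              crop_prob = 0.3, crop_fraction = 0.25,
                              noise_sd = 0.15, concavity_gain = 0.3) {
  stopifnot(is.data.frame(rates),
            all(c("region", "p_men", "p_women") %in% names(rates)))
  bad <- setdiff(rates$region, atlas_region_names())
  if (length(bad) > 0) stop("unknown region(s): ", paste(bad, collapse = ", "))
  if (any(rates$p_men < 0 | rates$p_men > 1 | rates$p_women < 0 | rates$p_women > 1))
    stop("probabilities must lie in [0, 1]")
  structure(list(rates = rates, defect_range = defect_range,
                 null_range = null_range, misalign_max_deg = misalign_max_deg,
                 misalign_max_mm = misalign_max_mm, crop_prob = crop_prob,
                 crop_fraction = crop_fraction, noise_sd = noise_sd,
                 concavity_gain = concavity_gain),
            class = "deviation_profile")
}

#' Default deviation profile: the reference cohort's observed rates
#'
#' Per-region, per-sex rates of > 3 mm deviation observed in a published
#' 60-subject CBCT-versus-smartphone-scan comparison (19 men, 41 women),
#' shipped as `inst/extdata/reference_cohort_rates.csv`.
#' @export
default_deviation_profile <- function() {
  r <- reference_cohort_rates()
  deviation_profile(data.frame(region = r$region,
                               p_men = r$pct_men / 100,
                               p_women = r$pct_women / 100))
}

#' Simulate a cohort of paired-scan subjects
#'
#' Draws per-subject defect patterns, misalignments, artifacts and
#' metadata. Sizes default to the reference study's composition (19 men,
#' 41 women). Scan-interval metadata is sampled on 0–10 days and
#' expression/artifact QC flags at a 95% pass rate, so the cohort filter
#' has genuine exclusions to perform. Each subject gets an independent seed
#' substream (`seed + subject index`), so changing the cohort size does not
#' reshuffle earlier subjects.
#'
#' @param n_men,n_women cohort composition (defaults 19 / 41).
#' @param profile a [deviation_profile()].
#' @param seed integer seed.
#' @param face_parameters base [face_params()] for every subject.
#' @param meshes if TRUE, meshes are built immediately (each case gains a
#'   `pair` element); if FALSE (default) call [build_case()] lazily.
#' @return list of cases; each case has `subject_id`, `sex` ("M"/"F"),
#'   `interval_days`, `expression_ok`, `artifact_ok`, `spec`
#'   (`perturbation_spec`), `truth_dev` (named per-region amplitudes, mm),
#'   `params`, `seed`.
#' @export
simulate_cohort <- function(n_men = 19, n_women = 41,
                            profile = default_deviation_profile(),
                            seed = 1L, face_parameters = face_params(),
                            meshes = FALSE) {
  stopifnot(n_men + n_women >= 1, inherits(profile, "deviation_profile"))
  sexes <- c(rep("M", n_men), rep("F", n_women))
  regions <- profile$rates$region
  cases <- vector("list", length(sexes))
  for (i in seq_along(sexes)) {
    case_seed <- as.integer(seed) + i
    cases[[i]] <- with_seed(case_seed, {
      p <- if (sexes[i] == "M") profile$rates$p_men else profile$rates$p_women
      defect <- rbinom(length(regions), 1, p) == 1
      amp <- ifelse(defect,
                    runif(length(regions), profile$defect_range[1], profile$defect_range[2]),
                    runif(length(regions), profile$null_range[1], profile$null_range[2]))
      names(amp) <- regions
      spec <- perturbation_spec(
        offsets = amp,
        noise_sd = profile$noise_sd,
        concavity_gain = profile$concavity_gain,
        misalign_angles = runif(3, -profile$misalign_max_deg, profile$misalign_max_deg),
        misalign_trans = runif(3, -profile$misalign_max_mm, profile$misalign_max_mm),
        forehead_crop = if (runif(1) < profile$crop_prob) profile$crop_fraction else 0)
      list(subject_id = sprintf("S%03d", i), sex = sexes[i],
           interval_days = sample(0:10, 1),
           expression_ok = runif(1) < 0.95,
           artifact_ok = runif(1) < 0.95,
           spec = spec, truth_dev = amp,
           params = face_parameters, seed = case_seed)
    })
  }
  if (meshes) cases <- lapply(cases, function(cs) { cs$pair <- build_case(cs); cs })
  cases
}

#' Materialize the meshes of a simulated case
#' @param case one element of a [simulate_cohort()] result.
#' @param min_region_vertices passed to [generate_face()].
#' @return a `face_pair`.
#' @export
build_case <- function(case, min_region_vertices = 20) {
  face <- generate_face(case$params, min_region_vertices = min_region_vertices)
  derive_pair(face, case$spec, seed = case$seed)
}

#' Cohort manifest as a data.frame
#' @param cases a [simulate_cohort()] result.
#' @export
cohort_manifest <- function(cases) {
  data.frame(subject_id = vapply(cases, `[[`, "", "subject_id"),
             sex = vapply(cases, `[[`, "", "sex"),
             interval_days = vapply(cases, `[[`, 0, "interval_days"),
             expression_ok = vapply(cases, `[[`, TRUE, "expression_ok"),
             artifact_ok = vapply(cases, `[[`, TRUE, "artifact_ok"))
}

#' Write a subject's case bundle to a directory
#'
#' Writes `shell.stl`, `scan.stl` (binary STL), `landmarks.txt` (name x y z
#' per line, both mesh frames), `atlas.csv` (scan `vertex_id,region`) and
#' `truth.csv` (per-region true deviation in mm).
#'
#' @param pair a `face_pair`.
#' @param dir output directory (created if needed).
#' @export
write_case_bundle <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stl(pair$shell, file.path(dir, "shell.stl"))
  write_stl(pair$scan, file.path(dir, "scan.stl"))
  lmk <- rbind(
    data.frame(frame = "shell", name = rownames(pair$shell_landmarks),
               x = pair$shell_landmarks[, 1], y = pair$shell_landmarks[, 2],
               z = pair$shell_landmarks[, 3]),
    data.frame(frame = "scan", name = rownames(pair$scan_landmarks),
               x = pair$scan_landmarks[, 1], y = pair$scan_landmarks[, 2],
               z = pair$scan_landmarks[, 3]))
  write.csv(lmk, file.path(dir, "landmarks.txt"), row.names = FALSE)
  # STL stores facets, not indexed vertices: re-reading scan.stl yields
  # vertices in welding (first-appearance) order. Renumber the atlas to
  # that ordering so atlas.csv matches the mesh as read back from disk.
  # Unreferenced vertices do not survive the STL roundtrip and are dropped.
  stl_order <- unique(as.vector(pair$scan$faces))
  at <- pair$scan_atlas[stl_order]
  write.csv(data.frame(vertex_id = seq_along(at),
                       region = ifelse(is.na(at), "", at)),
            file.path(dir, "atlas.csv"), row.names = FALSE)
  write.csv(data.frame(region = names(pair$truth$region_dev),
                       true_deviation_mm = as.numeric(pair$truth$region_dev)),
            file.path(dir, "truth.csv"), row.names = FALSE)
  write_transform(pair$truth$transform, file.path(dir, "misalignment.txt"))
  invisible(dir)
}
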