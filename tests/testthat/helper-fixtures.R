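# Shared phantom fixtures, generated once per test run and cached.
# Coarse (0.5 mm) phantoms drive the module-level tests; the acceptance
# tests build their own full-resolution (0.3 mm) cases.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

coarse_spec <- function(...) phantom_spec(spacing = 0.5, seed = 42, ...)

coarse_cbct <- function() {
  fixture("coarse_cbct", generate_cbct_phantom(coarse_spec()))
}

coarse_config <- function(...) pipeline_config(w = 9, ...)

coarse_sep <- function() {
  fixture("coarse_sep",
          separate_jaws(coarse_cbct()$volume, coarse_config()))
}

coarse_upper_ident <- function() {
  fixture("coarse_upper_ident", {
    ph <- coarse_cbct()
    sep <- coarse_sep()
    mvol <- voxel_volume(ph$volume$data * sep$assignment$upper,
                         spacing = ph$volume$spacing,
                         origin = ph$volume$origin)
    mip <- compute_mip(mvol, jaw = "upper")
    det <- detect_teeth_on_mip(mip, threshold = sep$threshold)
    prof <- extract_jaw_profile(mip, threshold = sep$threshold)
    prof <- estimate_midline(prof, delta_d = 0.6 / 0.5)
    det <- assign_fdi(det, prof)
    list(ph = ph, sep = sep, mip = mip, det = det, prof = prof)
  })
}

# full-resolution (0.3 mm) study-condition phantom, shared by the
# acceptance tests and the cascade comparisons
accept_cbct <- function() {
  fixture("accept_cbct", generate_cbct_phantom(phantom_spec(seed = 42)))
}

accept_run <- function() {
  fixture("accept_run", run_cbct(accept_cbct()$volume))
}

accept_sep <- function() {
  fixture("accept_sep", separate_jaws(accept_cbct()$volume))
}

# full-resolution identification of the upper jaw (held-out phantom for the
# cascade comparison: a different seed from accept_cbct)
heldout_ident <- function() {
  fixture("heldout_ident", {
    ph <- generate_cbct_phantom(phantom_spec(seed = 9))
    sep <- separate_jaws(ph$volume)
    mvol <- voxel_volume(ph$volume$data * sep$assignment$upper,
                         spacing = ph$volume$spacing,
                         origin = ph$volume$origin)
    mip <- compute_mip(mvol, jaw = "upper")
    det <- detect_teeth_on_mip(mip, threshold = sep$threshold)
    prof <- extract_jaw_profile(mip, threshold = sep$threshold)
    prof <- estimate_midline(prof, delta_d = 2)
    det <- assign_fdi(det, prof)
    list(ph = ph, mip = mip, det = det, prof = prof)
  })
}

# paired 1-stage vs 3-stage landmark errors (mm) over one jaw
cascade_paired_errors <- function(fx) {
  tt <- fx$ph$truth$teeth[fx$ph$truth$teeth$jaw == "upper", ]
  cen <- truth_centers_px(fx$ph$truth, fx$ph$volume, "upper")
  dd <- fx$det$detections
  sp <- fx$ph$volume$spacing[1]
  e1 <- e3 <- numeric(0)
  for (i in seq_len(nrow(tt))) {
    j <- dd$id[which.min((dd$cx - cen[i, 1])^2 + (dd$cy - cen[i, 2])^2)]
    roi <- crop_tooth_roi(fx$mip$data, fx$det, j, fx$prof,
                          spacing = fx$ph$volume$spacing[1:2])
    mes <- c((tt$mes_x[i] - fx$ph$volume$origin[1]) / sp + 0.5,
             (tt$mes_y[i] - fx$ph$volume$origin[2]) / sp + 0.5)
    dis <- c((tt$dis_x[i] - fx$ph$volume$origin[1]) / sp + 0.5,
             (tt$dis_y[i] - fx$ph$volume$origin[2]) / sp + 0.5)
    err <- function(pair) {
      lo <- pair$lo + roi$offset; hi <- pair$hi + roi$offset
      min(sqrt(sum((lo - mes)^2)) + sqrt(sum((hi - dis)^2)),
          sqrt(sum((hi - mes)^2)) + sqrt(sum((lo - dis)^2))) / 2 * sp
    }
    e1 <- c(e1, err(run_cascade(cascade_detector(1), roi)))
    e3 <- c(e3, err(run_cascade(cascade_detector(3), roi)))
  }
  list(e1 = e1, e3 = e3)
}

scan_fix <- function() {
  fixture("scan_fix", generate_scan_phantom(phantom_spec(seed = 42),
                                            jaw = "upper"))
}

scan_model <- function() {
  fixture("scan_model", frnn_model(phantom_color_samples(seed = 1)))
}

scan_seg <- function() {
  fixture("scan_seg",
          teeth_cloud_and_depthmap(scan_fix()$cloud, scan_model()))
}

# truth tooth centers in 1-based pixel coordinates of a volume grid
truth_centers_px <- function(truth, volume, jaw) {
  tt <- truth$teeth[truth$teeth$jaw == jaw, ]
  cbind((tt$cx - volume$origin[1]) / volume$spacing[1] + 0.5,
        (tt$cy - volume$origin[2]) / volume$spacing[2] + 0.5)
}

cross_assignment_rate <- function(assignment, jaw_label) {
  (sum(assignment$upper & jaw_label == 2L) +
     sum(assignment$lower & jaw_label == 1L)) /
    max(1L, sum(assignment$upper) + sum(assignment$lower))
}
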