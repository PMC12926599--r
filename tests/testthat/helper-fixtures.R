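# Shared fixtures. Everything is generated in code; heavier objects are
# memoised in this environment so multiple test files can reuse them.
.fixtures <- new.env(parent = emptyenv())

# small 5 mm phantom used by most dose/planning tests
small_phantom <- function() {
  if (is.null(.fixtures$small_phantom)) {
    sh <- c(40L, 32L, 34L)
    g <- voxel_grid(sh, spacing = c(5, 5, 5), origin = -(sh - 1) * 5 / 2)
    .fixtures$small_phantom <- generate_phantom(grid = g)
  }
  .fixtures$small_phantom
}

# default 3 mm phantom (deformation suite)
default_phantom <- function() {
  if (is.null(.fixtures$default_phantom)) {
    .fixtures$default_phantom <- generate_phantom()
  }
  .fixtures$default_phantom
}

# hand-built rectangular phantom: uniform material in a box, for oracle tests
# where analytic geometry matters (slabs, water tanks)
box_phantom <- function(shape = c(40L, 16L, 16L), spacing = c(2, 2, 2),
                        hu_value = 0, lung_x = NULL, tumor_x = NULL) {
  g <- voxel_grid(shape, spacing = spacing, origin = -(shape - 1) * spacing / 2)
  hu <- array(hu_value, shape)
  tr <- function(ix) {
    m <- array(FALSE, shape)
    if (!is.null(ix)) m[ix, , ] <- TRUE
    m
  }
  lung <- tr(lung_x)
  tumor <- tr(tumor_x)
  structure(list(
    grid = g, hu = hu,
    structures = list(CTV = tumor, lung_ipsi = lung & !tumor,
                      lung_contra = array(FALSE, shape),
                      heart = array(FALSE, shape),
                      esophagus = array(FALSE, shape),
                      aorta = array(FALSE, shape),
                      spinal_cord = array(FALSE, shape),
                      chest_wall = array(FALSE, shape),
                      body = array(TRUE, shape)),
    meta = list(tumor_diameter_mm = NA, tumor_center_mm = c(0, 0, 0),
                laterality = "right", noise_sd = 0, seed = 1L,
                tumor_wall_gap_mm = NA),
    cache = new.env(parent = emptyenv())),
    class = "bh_phantom")
}

# engine/objective settings for fast planning tests (reduced spot grids)
test_pars <- function() dose_engine_params(layer_spacing_mm = 8, spot_spacing_mm = 8)
test_obj <- function() objective_config(n_shell = 400, n_cw = 200)

# the full small study: six normalized plans on the 5 mm phantom plus
# probabilistic evaluations on both reproducibility sets (200 treatments per
# plan per set) — built once, shared by the planning and evaluation suites
study_plans <- function() {
  if (is.null(.fixtures$plans)) {
    ph <- small_phantom()
    .fixtures$plans <- lapply(
      stats::setNames(planning_strategies()$name, planning_strategies()$name),
      function(nm) plan_strategy(ph, nm, pars = test_pars(), obj = test_obj()))
  }
  .fixtures$plans
}

study_evaluations <- function(n_samples = 200L) {
  if (is.null(.fixtures$evals)) {
    plans <- study_plans()
    ph <- small_phantom()
    out <- list()
    for (set in c("A", "B")) {
      ctx <- evaluation_context(ph, uncertainty_model(), set)
      for (nm in names(plans)) {
        # common random numbers across A and B: the same seed pairs the
        # underlying draws, so the A-vs-B comparison is variance-reduced
        out[[paste0(nm, "_", set)]] <-
          evaluate_plan(plans[[nm]], set, n_samples = n_samples,
                        seed = 20L, ctx = ctx)
      }
    }
    .fixtures$evals <- out
  }
  .fixtures$evals
}

# independent brute-force Dx% oracle: descending sort, linear interpolation
# at position n * x/100 + 0.5 between order statistics
brute_dx <- function(dose, x) {
  if (x <= 0) return(max(dose))
  s <- sort(dose, decreasing = TRUE)
  n <- length(s)
  h <- n * x / 100 + 0.5
  if (h <= 1) return(s[1])
  if (h >= n) return(s[n])
  lo <- floor(h)
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}
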