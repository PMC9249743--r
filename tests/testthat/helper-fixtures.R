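# Shared fixtures.  Expensive objects are built once per test run and
# memoised in this environment; everything is generated in code (no
# stored data files).

options(cnnforest.verbose = FALSE)

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# tiny cohort for fast unit tests: 16 x 16 images, 10 + 10 patients
tiny_cohort <- function(lesion = 0.8, seed = 1L) {
  memo(sprintf("tiny_%s_%d", lesion, seed),
       generate_cohort(cohort_config(
         n_healthy_patients = 10L, n_cad_patients = 10L,
         images_per_patient = 4L, image_size = c(16L, 16L),
         lesion_intensity = lesion, lesion_radius_px = 3L,
         noise_sd = 0.05, seed = seed)))
}

# small pipeline config matching the tiny cohort
tiny_config <- function(seed = 1L, n_cnns = 2L, folds = 2L) {
  pipeline_config(
    n_cnns = n_cnns, folds = folds,
    cnn_spec = cnn_spec(input_shape = c(16L, 16L), epochs = 1L,
                        batch_size = 4L, optimizer = "adam"),
    forest_params = forest_params(n_trees = 5L),
    global_seed = seed)
}

# one trained extractor on the tiny separable cohort, reused across tests
tiny_extractor <- function() {
  memo("tiny_extractor", {
    ds <- tiny_cohort()
    spec <- cnn_spec(input_shape = c(16L, 16L), epochs = 2L,
                     batch_size = 4L, optimizer = "adam")
    ids <- ds$sample_id
    set.seed(404)
    val <- sample(ids, 16L)
    list(ds = ds,
         extractor = train_cnn(setdiff(ids, val), val, ds, spec, 11L),
         val = val)
  })
}

# a random nested tree for oracle tests (balanced random splits)
random_tree <- function(n_features, depth) {
  if (depth == 0L || stats::runif(1) < 0.3)
    return(list(type = "leaf", class = sample(0:1, 1L),
                counts = c(sample(0:5, 1L), sample(0:5, 1L))))
  list(type = "internal",
       feature_col = sample.int(n_features, 1L),
       threshold = stats::runif(1),
       left = random_tree(n_features, depth - 1L),
       right = random_tree(n_features, depth - 1L))
}

# desk-scale runs shared by the acceptance tests (method + baseline per
# seed); computed lazily, each ~2.5 min on one CPU
desk_runs <- function(seed) {
  memo(sprintf("desk_%d", seed), {
    ds <- generate_cohort(cohort_config(seed = seed))
    cfg <- desk_pipeline_config(global_seed = seed)
    t0 <- proc.time()
    method <- run_pipeline(ds, cfg, keep_models = FALSE)
    elapsed <- (proc.time() - t0)[["elapsed"]]
    baseline <- run_baseline_cnn(ds, method$plan, cfg)
    list(method = method, baseline = baseline, elapsed = elapsed)
  })
}
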