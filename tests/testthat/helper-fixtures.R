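# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# default-scale reference and cohorts (the study conditions)
fix_reference <- function() {
  cached("reference", function() generate_reference(seed = 101))
}

fix_sim <- function() {
  cached("sim", function() generate_cohorts(sim_config(seed = 101),
                                            fix_reference()))
}

# platform Z-scored shared-panel matrix over all samples
fix_zmat <- function() {
  cached("zmat", function() {
    sim <- fix_sim()
    z1 <- zscore_by_platform(sim$expr1, rep("V3", ncol(sim$expr1)))
    z2 <- zscore_by_platform(sim$expr2, rep("V4", ncol(sim$expr2)))
    shared <- intersect(rownames(z1), rownames(z2))
    cbind(z1[shared, ], z2[shared, ])[, sim$samples$sample_id]
  })
}

fix_signatures <- function() {
  cached("signatures", function() {
    ref <- fix_reference()
    sigs <- lapply(ref$cell_types, function(ct)
      select_signature_genes(ref, ct))
    names(sigs) <- ref$cell_types
    sigs
  })
}

fix_scores <- function() {
  cached("scores", function()
    compute_signature_scores(fix_zmat(), fix_signatures()))
}

# small smooth expression matrix for toy tests
toy_matrix <- function(n_genes, n_samples, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n_genes * n_samples, mean = 8, sd = sd),
         nrow = n_genes,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

# a 400-patient ALS survival fixture with planted genes
fix_surv <- function() {
  cached("surv", function() {
    set.seed(202)
    n <- 400; g <- 2000
    samples <- tibble::tibble(
      sample_id = sprintf("p%03d", seq_len(n)),
      cohort = sample(c("C1", "C2"), n, replace = TRUE),
      group = "ALS",
      sex = sample(c("M", "F"), n, replace = TRUE),
      age = stats::rnorm(n, 60, 10),
      onset_site = sample(c("spinal", "bulbar"), n, replace = TRUE,
                          prob = c(0.7, 0.3)),
      surv_time = NA_real_, event = NA_integer_)
    expr <- matrix(stats::rnorm(g * n), g, n,
                   dimnames = list(sprintf("g%04d", seq_len(g)),
                                   samples$sample_id))
    sv <- generate_survival(samples, expr, sim_config(seed = 202),
                            seed = 203)
    list(samples = sv$samples, expr = expr, truth = sv$truth)
  })
}
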