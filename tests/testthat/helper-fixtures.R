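# Shared simulated fixtures, memoised across test files (test_dir runs the
# whole suite in one session).

.fixture_cache <- new.env(parent = emptyenv())

shared_sim <- function(n = 1000, seed = 101) {
  key <- sprintf("sim_%d_%d", n, seed)
  if (!exists(key, envir = .fixture_cache))
    assign(key, simulate_cohort(sim_config(n_patients = n, seed = seed)),
           envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small helper: build a one-sample panel data frame with exact counts
make_panel <- function(sample_id, alt, ref, normals_depth,
                       informative = TRUE) {
  n <- length(alt)
  data.frame(sample_id = sample_id,
             locus_id = sprintf("L%02d", seq_len(n)),
             chrom = "chr3", pos = seq_len(n) * 1e6,
             ref_count = ref, alt_count = alt,
             normals_depth = rep_len(normals_depth, n),
             informative = rep_len(informative, n),
             stringsAsFactors = FALSE)
}
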