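## One shared desk-scale fixture (two libraries of 10,000 reads, seed 1),
## built once per test run and reused by the module and acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

test_fixture <- function() {
  if (is.null(.fixture_cache$sim)) {
    cfg <- simulation_config(seed = 1L,
                             n_reads_per_library = c(10000L, 10000L))
    ref <- build_reference(cfg)
    sim <- simulate_libraries(cfg, ref)
    .fixture_cache$cfg <- cfg
    .fixture_cache$ref <- ref
    .fixture_cache$sim <- sim
  }
  list(cfg = .fixture_cache$cfg, ref = .fixture_cache$ref,
       sim = .fixture_cache$sim)
}

## Cleaned + collapsed tags for the shared fixture (memoised).
test_fixture_tags <- function() {
  if (is.null(.fixture_cache$tags)) {
    fx <- test_fixture()
    cl1 <- clean_reads(fx$sim$reads$lib1, fx$cfg$adapter_3p,
                       fx$cfg$adapter_5p)
    cl2 <- clean_reads(fx$sim$reads$lib2, fx$cfg$adapter_3p,
                       fx$cfg$adapter_5p)
    .fixture_cache$clean <- list(cl1 = cl1, cl2 = cl2)
    .fixture_cache$tags <- collapse_tags(list(lib1 = unname(cl1$clean),
                                              lib2 = unname(cl2$clean)))
  }
  list(clean = .fixture_cache$clean, tags = .fixture_cache$tags)
}
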