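# The published-course fixture is deterministic; build it once per run.
.fixture_cache <- new.env(parent = emptyenv())

published_fixture <- function() {
  if (is.null(.fixture_cache$built))
    .fixture_cache$built <- build_published_kb()
  .fixture_cache$built
}

tx <- function(x) paste0("TXPOX:", x)
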