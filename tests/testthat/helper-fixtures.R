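# Shared fixtures, built once per session on first use. Seeds are fixed so
# every fixture is reproducible.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# repeat a codon L times and append a stop
codon_cds <- function(codon, L, stop = "TAA") paste0(strrep(codon, L), stop)

# 1000-pair synthetic proteome at realistic protein lengths
big_proteome <- function() {
  fixture("big_proteome", function() {
    generate_proteome(1000, "lognormal:300,0.4", codon_usage = "uniform", seed = 101)
  })
}

big_cache <- function() {
  fixture("big_cache", function() profile_cache(big_proteome(), targets = "PUR"))
}

# 100 independent searches on the big proteome (landscape ensemble)
big_ensemble <- function() {
  fixture("big_ensemble", function() {
    cache <- big_cache()
    lapply(201:300, function(s) run_mc(cache, mc_config(target = "PUR"), seed = s))
  })
}

# ten independent searches on the big proteome (the funnel / recovery ensemble)
big_runs <- function() {
  big_ensemble()[1:10]
}

# small proteome for cheap landscape ensembles
small_proteome <- function() {
  fixture("small_proteome", function() {
    generate_proteome(60, "lognormal:150,0.3", codon_usage = "uniform", seed = 301)
  })
}

small_cache <- function() {
  fixture("small_cache", function() profile_cache(small_proteome(), targets = "PUR"))
}

# 100 independent searches on the small proteome
small_runs <- function() {
  fixture("small_runs", function() {
    cache <- small_cache()
    lapply(401:500, function(s) run_mc(cache, mc_config(target = "PUR"), seed = s))
  })
}

# paths where a user can drop the original whole-proteome datasets
# (space-separated dialect, one `id cds protein` record per line)
s1_dataset_path <- function(organism) {
  file.path(
    system.file("extdata", package = "scalescape"),
    "s1_dataset", paste0(organism, ".txt")
  )
}

# sequence columns only, attributes stripped (for round-trip comparisons)
plain_df <- function(p) {
  data.frame(id = p$id, cds = p$cds, protein = p$protein)
}
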