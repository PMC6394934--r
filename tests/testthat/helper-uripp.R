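# Shared fixtures: the bundled registry is immutable, load it once.
bundled <- load_panel()

# Independent sort-based quantile oracle (linear interpolation between order
# statistics), deliberately not calling stats::quantile.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Noiseless single-Gaussian channel on the generator's grid.
gaussian_trace <- function(rt, height, sigma = 0.05, dt = 0.005,
                           halfwidth = 1.5) {
  t <- seq(rt - halfwidth, rt + halfwidth, by = dt)
  data.frame(time_min = t,
             intensity = height * exp(-(t - rt)^2 / (2 * sigma^2)))
}

# Panel copy with one mutation applied to the transition table, written to a
# temporary directory so load_panel() exercises its parse/validation path.
mutated_panel_dir <- function(mutate) {
  dir <- tempfile("panel")
  write_panel(bundled, dir)
  tr <- read.delim(file.path(dir, "panel_transitions.tsv"),
                   stringsAsFactors = FALSE, colClasses = "character",
                   na.strings = NULL)
  tr <- mutate(tr)
  write.table(tr, file.path(dir, "panel_transitions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dir
}
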