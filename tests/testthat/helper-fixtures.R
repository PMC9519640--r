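# Shared fixtures for the suite, built in code.

# Reference cross-tab counts (NIRIS category x 6-month vital status,
# N = 3031): per-category totals and deaths.
ref_counts <- function() {
  list(n = c(320, 225, 1297, 526, 663),
       deaths = c(27, 12, 220, 142, 309))
}

ref_xtab <- function() {
  rc <- ref_counts()
  crosstab(0:4, events = rc$deaths, nonevents = rc$n - rc$deaths)
}

# Discrete lattice over the Helsinki-relevant findings dimensions.
helsinki_lattice <- function(volumes = c(0, 0.3, 1, 16, 21, 26, 60, 201)) {
  grid <- expand.grid(edh = volumes, sdh = volumes, ich = volumes,
                      ivh = c(FALSE, TRUE),
                      cist = c("normal", "compressed", "obliterated"),
                      stringsAsFactors = FALSE)
  ct_findings(edh_volume_cm3 = grid$edh, sdh_volume_cm3 = grid$sdh,
              ich_contusion_volume_cm3 = grid$ich,
              ivh_present = grid$ivh, suprasellar_cisterns = grid$cist)
}

# Small cohort with a clean logistic structure for metric tests.
toy_logit_data <- function(n = 300, beta = c(-1, 1.2), seed = 11) {
  set.seed(seed)
  x <- rnorm(n)
  p <- plogis(beta[1] + beta[2] * x)
  list(x = x, y = runif(n) < p, p = p)
}
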