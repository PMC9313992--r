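# Shared fixtures: tiny cohorts, graphs and model instances built in code.

tiny_spec <- function(n = 60, seed = 7, ...) {
  synthetic_spec(n_patients = n, prevalence = 0.2, duplicate_rate = 0,
                 missing_rate = 0, outlier_rate = 0, seed = seed, ...)
}

# small symmetric 0/1 adjacency with zero diagonal
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(rbinom(n * n, 1, p), n, n)
  A <- pmax(A, t(A))
  diag(A) <- 0
  A
}

# minimal cohort data.frame for preprocessing tests
toy_cohort <- function(ids, ts, age, smoking, label = rep(0, length(ids))) {
  data.frame(patient_id = ids, timestamp = ts, label = label,
             age = age, smoking = smoking, stringsAsFactors = FALSE)
}

toy_schema <- function() {
  data.frame(name = c("age", "smoking"),
             kind = c("quantitative", "qualitative"),
             lower = c(18, NA), upper = c(110, NA),
             stringsAsFactors = FALSE)
}

# deterministic tiny AM-GCN instance (no dropout) for oracle and gradient tests
tiny_instance <- function(seed = 3, N = 6, D = 4) {
  set.seed(seed)
  X <- matrix(rnorm(N * D), N, D)
  Ap <- random_adjacency(N)
  Af <- random_adjacency(N)
  y <- rep_len(c(0L, 1L), N)
  cfg <- train_config(dropout = 0, nhid1 = 3, nhid2 = 2, att_hidden = 3,
                      beta = 1e-3, theta = 0.5, seed = seed)
  params <- chdgcn:::init_amgcn_params(D, cfg)
  list(X = X, Ap = Ap, Af = Af, Pp = normalize_adjacency(Ap),
       Pf = normalize_adjacency(Af), y = y, mask = seq_len(N - 1),
       cfg = cfg, params = params)
}
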