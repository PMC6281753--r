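# Independent one-component NIPALS PLS1 oracle, written directly from the
# textbook algorithm; used to cross-check the OPLS fit with no orthogonal
# components. Deliberately shares no code with the package internals.
pls1_one_component <- function(X, y) {
  w <- drop(t(X) %*% y)
  w <- w / sqrt(sum(w^2))
  t_score <- drop(X %*% w)
  p <- drop(t(X) %*% t_score) / sum(t_score^2)
  c_load <- sum(y * t_score) / sum(t_score^2)
  list(w = w, t = t_score, p = p, c = c_load, b = c_load * w)
}

scale_uv <- function(m) scale(m, center = TRUE, scale = apply(m, 2, sd))

center_uv_vec <- function(v) (v - mean(v)) / sd(v)

# Build a 2 CON + 2 CWP spot table whose group means are exactly the
# requested values (each group gets mean +/- 10%).
group_mean_table <- function(spots, mean_con, mean_cwp) {
  vals <- rbind(mean_con * 0.9, mean_con * 1.1, mean_cwp * 0.9, mean_cwp * 1.1)
  spot_table(vals, sample_ids = c("CON1", "CON2", "CWP1", "CWP2"),
             spot_numbers = spots)
}

group_mean_clinical <- function() {
  clinical_table(c("CON1", "CON2", "CWP1", "CWP2"),
                 c("CON", "CON", "CWP", "CWP"),
                 nrs = c(0, 0, 4, 6), hads_total = c(2, 4, 12, 16),
                 bmi = c(23, 25, 25, 27), age = c(40, 42, 48, 50))
}

# A minimal model report carrying just a significant-spot set, for workflow
# operations that only consume that set.
stub_report <- function(name, spots, group = "CON") {
  structure(list(model_name = name, group = group,
                 significant_spots = data.frame(spot_number = as.integer(spots))),
            class = "model_report")
}

random_problem <- function(n, k, seed) {
  set.seed(seed)
  list(x = matrix(rnorm(n * k), n, k), y = rnorm(n))
}
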