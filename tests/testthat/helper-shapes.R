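# Small in-code fixtures shared across tests.

tetra_shape <- function(shape_id = "tetra") {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  topo <- tri_topology(4, rbind(c(0, 1, 2), c(0, 1, 3), c(0, 2, 3), c(1, 2, 3)))
  corresponded_shape(v, topo, shape_id)
}

rotation_z <- function(angle) {
  rbind(c(cos(angle), -sin(angle), 0),
        c(sin(angle), cos(angle), 0),
        c(0, 0, 1))
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_res)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigid_motion <- function(shape, R, tr) {
  corresponded_shape(shape$vertices %*% t(R) +
                       matrix(tr, nrow(shape$vertices), 3, byrow = TRUE),
                     shape$topology, shape$shape_id)
}

random_shape <- function(n_vertices = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntri <- n_vertices - 2L
  tri <- cbind(seq_len(ntri), seq_len(ntri) + 1L, seq_len(ntri) + 2L) - 1L
  corresponded_shape(matrix(rnorm(3 * n_vertices, sd = 10), ncol = 3),
                     tri_topology(n_vertices, tri))
}

# 2-subject, 2-knee, 3-timepoint cohort with simple deterministic values
toy_cohort <- function() {
  grid <- expand.grid(timepoint_months = c(0, 6, 12),
                      knee = c("index", "control"),
                      subject_id = c("S01", "S02"),
                      stringsAsFactors = FALSE)
  grid$sex <- ifelse(grid$subject_id == "S01", "female", "male")
  grid$icrs_grade <- ifelse(grid$knee == "index", 3L, 2L)
  grid$bscore <- 1 + 0.1 * grid$timepoint_months / 6 +
    ifelse(grid$knee == "control", 0.05, 0) +
    ifelse(grid$subject_id == "S02", 0.5, 0)
  for (r in thickness_regions)
    grid[[paste0("thick_", r)]] <- 2 + 0.01 * grid$timepoint_months
  grid[, c("subject_id", "knee", "sex", "timepoint_months", "icrs_grade",
           "bscore", paste0("thick_", thickness_regions))]
}
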