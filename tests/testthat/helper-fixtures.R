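# Geometric fixtures built in code, plus independent oracles used to check
# the package's analytic computations.

regular_polygon <- function(n, r, center = c(0, 0)) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
}

ellipse_polygon <- function(a, b, n = 256, center = c(0, 0), angle = 0) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(theta)
  y <- b * sin(theta)
  rot <- cbind(x * cos(angle) - y * sin(angle),
               x * sin(angle) + y * cos(angle))
  sweep(rot, 2, center, `+`)
}

# random star-convex polygon; uses the ambient RNG stream
star_polygon <- function(n_vertices, mean_radius, irregularity) {
  theta <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- mean_radius * (1 + irregularity * stats::runif(n_vertices, -1, 1))
  cbind(r * cos(theta), r * sin(theta))
}

# pixel-counting area oracle: counts grid-cell centers inside the polygon
# by even-odd ray crossing; independent of the package's shoelace kernel
raster_area <- function(v, spacing = 0.1) {
  xs <- seq(min(v[, 1]) - spacing, max(v[, 1]) + spacing, by = spacing)
  ys <- seq(min(v[, 2]) - spacing, max(v[, 2]) + spacing, by = spacing)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  inside <- rep(FALSE, length(px))
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  sum(inside) * spacing^2
}

# direct two-group Mantel-Cox evaluation (sum of O-E and hypergeometric
# variances over event times); independent of the package's k-group kernel
hand_logrank_chisq <- function(time, event, g) {
  stopifnot(all(g %in% 0:1))
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    n1 <- sum(time >= t & g == 1)
    n0 <- sum(time >= t & g == 0)
    n <- n1 + n0
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n0 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# a 6-lesion feature table exercising both inclusion rules
six_lesion_fixture <- function() {
  mk <- function(id, organ, a, b) {
    f <- shape_features(polygon2d(ellipse_polygon(a, b)))
    data.frame(patient_id = "P1", timepoint = "baseline", lesion_id = id,
               organ = organ, surface = f$surface, major_axis = f$major_axis,
               minor_axis = f$minor_axis, volume = f$volume,
               stringsAsFactors = FALSE)
  }
  rbind(mk("L1", "lymph_node", 10, 4.5),  # minor 9 mm -> dropped
        mk("L2", "lung", 1.25, 1),        # major 2.5 mm -> dropped
        mk("L3", "liver", 7.5, 5),        # major 15 mm -> kept
        mk("L4", "lymph_node", 12, 6),    # minor 12 mm -> kept
        mk("L5", "bone", 4, 3),           # kept
        mk("L6", "carcinosis", 9, 2))     # kept
}

# minimal two-patient cohort with hand-computable parameter values
tiny_cohort <- function() {
  sphere10 <- shape_features(polygon2d(regular_polygon(256, 10)))
  lesions <- rbind(
    data.frame(patient_id = "A", timepoint = "baseline", lesion_id = "L1",
               organ = "liver", surface = 100, major_axis = 12,
               minor_axis = 9, volume = 600),
    data.frame(patient_id = "A", timepoint = "baseline", lesion_id = "L2",
               organ = "liver", surface = 50, major_axis = 9, minor_axis = 6,
               volume = 200),
    data.frame(patient_id = "A", timepoint = "eval1", lesion_id = "L1",
               organ = "liver", surface = 150, major_axis = 14,
               minor_axis = 11, volume = 1100),
    data.frame(patient_id = "B", timepoint = "baseline", lesion_id = "L1",
               organ = "lung", surface = 200, major_axis = 18,
               minor_axis = 14, volume = 1866.6667),
    data.frame(patient_id = "B", timepoint = "eval1", lesion_id = "L1",
               organ = "lung", surface = 100, major_axis = 12,
               minor_axis = 10, volume = 666.6667),
    data.frame(patient_id = "B", timepoint = "eval1", lesion_id = "L2",
               organ = "bone", surface = 30, major_axis = 7, minor_axis = 5,
               volume = 100))
  blood <- data.frame(
    patient_id = c("A", "A", "B", "B"),
    timepoint = c("baseline", "eval1", "baseline", "eval1"),
    neutrophils = c(5, 6, 3.3, 2.0),
    lymphocytes = c(1, 1, 1.1, 1.0),
    recist_sum_mm = c(40, 50, 60, 45),
    stringsAsFactors = FALSE)
  list(lesions = lesions, blood = blood)
}
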