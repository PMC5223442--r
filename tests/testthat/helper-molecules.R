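# toy molecules built in code; geometries are idealised but chemically sane

toy_methane <- function(id = "methane") {
  h <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 1.09 / sqrt(3)
  mol3d(id,
        data.frame(element = c("C", rep("H", 4)),
                   x = c(0, h[, 1]), y = c(0, h[, 2]), z = c(0, h[, 3])),
        data.frame(from = 1L, to = 2:5, order = 1))
}

toy_water <- function(id = "water") {
  mol3d(id,
        data.frame(element = c("O", "H", "H"),
                   x = c(0, 0.757, -0.757), y = c(0, 0.586, 0.586), z = 0),
        data.frame(from = 1L, to = 2:3, order = 1))
}

toy_methanol <- function(id = "methanol") {
  mol3d(id,
        data.frame(element = c("C", "O", "H", "H", "H", "H"),
                   x = c(0, 1.43, 1.76, -0.51, -0.51, -0.36),
                   y = c(0, 0, 0.89, 0.89, -0.89, 0),
                   z = c(0, 0, 0, 0.36, 0.36, -1.03)),
        data.frame(from = c(1L, 2L, 1L, 1L, 1L), to = c(2L, 3L, 4L, 5L, 6L),
                   order = 1))
}

toy_benzene <- function(id = "benzene") {
  ang <- (0:5) * pi / 3
  atoms <- data.frame(element = c(rep("C", 6), rep("H", 6)),
                      x = c(1.39 * cos(ang), 2.48 * cos(ang)),
                      y = c(1.39 * sin(ang), 2.48 * sin(ang)),
                      z = 0)
  bonds <- rbind(data.frame(from = 1:6, to = c(2:6, 1L), order = 4),
                 data.frame(from = 1:6, to = 7:12, order = 1))
  mol3d(id, atoms, bonds)
}

toy_acetate <- function(id = "acetate") {
  atoms <- data.frame(
    element = c("C", "C", "O", "O", "H", "H", "H"),
    x = c(0, 1.52, 2.16, 2.10, -0.52, -0.52, -0.36),
    y = c(0, 0, 1.05, -1.08, 0.89, -0.89, 0),
    z = c(0, 0, 0, 0, 0.36, 0.36, -1.03),
    formal = c(0L, 0L, 0L, -1L, 0L, 0L, 0L))
  bonds <- data.frame(from = c(1L, 2L, 2L, 1L, 1L, 1L),
                      to = c(2L, 3L, 4L, 5L, 6L, 7L),
                      order = c(1, 2, 1, 1, 1, 1))
  mol3d(id, atoms, bonds)
}

# ethanol with standard topology; charges depend only on the bond graph
toy_ethanol <- function(id = "ethanol") {
  atoms <- data.frame(
    element = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
    x = c(0.94, 2.46, 2.94, 0.56, 0.55, 0.56, 2.85, 2.84, 2.60),
    y = c(-0.07, -0.07, 0.29, -0.33, -0.78, 0.92, -1.06, 0.65, -0.36),
    z = c(0.04, 0.03, -1.25, 1.03, -0.70, -0.24, 0.29, 0.76, -1.89))
  bonds <- data.frame(from = c(1L, 2L, 1L, 1L, 1L, 2L, 2L, 3L),
                      to = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L),
                      order = 1)
  mol3d(id, atoms, bonds)
}

# n random points as a bond-less "molecule", for alignment tests
toy_points <- function(xyz, id = "pts", element = "C") {
  mol3d(id, data.frame(element = element, x = xyz[, 1], y = xyz[, 2],
                       z = xyz[, 3]))
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  rotation_matrix(ax, stats::runif(1, 0, 2 * pi))
}
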