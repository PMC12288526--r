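#' Port locations in arena coordinates
#'
#' Center, left and right response ports along the back wall of the
#' 20 x 20 cm arena (x, y in cm).
#' @param arena_cm Arena size (width, height) in cm.
#' @return 3 x 2 matrix with rownames `center`, `left`, `right`.
#' @export
port_locations <- function(arena_cm = c(20, 20)) {
  m <- rbind(center = c(arena_cm[1] / 2, 0.8),
             left = c(arena_cm[1] * 0.2, 0.8),
             right = c(arena_cm[1] * 0.8, 0.8))
  colnames(m) <- c("x", "y")
  m
}

.ar1 <- function(n, phi, sd_innov) {
  as.numeric(stats::filter(stats::rnorm(n, sd = sd_innov), phi,
                           method = "recursive"))
}

#' Simulate tracking streams for a session
#'
#' Generates chest-position trajectories, head-orientation angles, and
#' latent-movement factors with surrogate video / motion-energy component
#' time courses, all on the 30 Hz neural frame grid.
#'
#' The chest follows a smoothed random walk that is pulled toward the center
#' port around trial initiation and fixation, and toward the chosen side
#' port around the choice report and outcome; positions are reflected at the
#' arena walls. Yaw spans the full 360 degrees as a wrapped random walk;
#' pitch and roll are bounded smooth processes. The latent movement factors
#' are zero-mean AR(1) processes; with `coupling > 0` the first factors
#' additionally load on movement speed and center-port proximity, emulating
#' task-locked components of the behavioral video. Surrogate video and
#' motion-energy components are random linear mixtures of the factors plus
#' independent noise.
#'
#' @param table Trial table.
#' @param n_frames Number of frames; defaults to covering the session.
#' @param frame_rate Frames per second.
#' @param arena_cm Arena size (cm).
#' @param n_factors Number of latent movement factors.
#' @param n_components Number of surrogate video (and motion-energy)
#'   components.
#' @param coupling Coupling in `[0, 1]` between latent factors and task
#'   events (0 = independent).
#' @param seed Optional RNG seed.
#' @return List with `chest_xy` (frames x 2, cm), `head_angles` (frames x 3:
#'   yaw in `[0, 360)`, pitch, roll in degrees), `video_svd` and `motion_svd`
#'   (frames x `n_components`), and `latent` (factors and loadings).
#' @export
simulate_tracking <- function(table, n_frames = NULL, frame_rate = 30,
                              arena_cm = c(20, 20), n_factors = 5,
                              n_components = 200, coupling = 0.3,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_frames))
    n_frames <- as.integer(ceiling((max(table$t_outcome_end, na.rm = TRUE) + 2) *
                                     frame_rate))
  ports <- port_locations(arena_cm)

  # per-frame target: center port around initiation/fixation, chosen side
  # port around report/outcome, otherwise free wandering
  target <- matrix(NA_real_, n_frames, 2)
  f_of <- function(t) pmax(1L, pmin(n_frames, as.integer(round(t * frame_rate)) + 1L))
  for (i in seq_len(nrow(table))) {
    a <- f_of(table$t_init[i] - 1.0)
    b <- f_of(if (is.na(table$t_center_exit[i])) table$t_init[i] + 0.5
              else table$t_center_exit[i])
    target[a:b, ] <- rep(ports["center", ], each = b - a + 1L)
    if (table$completed[i]) {
      p <- if (table$choice[i] == "right") "right" else "left"
      a2 <- f_of(table$t_choice_report[i] - 0.4)
      b2 <- f_of(table$t_outcome_end[i])
      target[a2:b2, ] <- rep(ports[p, ], each = b2 - a2 + 1L)
    }
  }

  chest <- matrix(0, n_frames, 2)
  pos <- c(arena_cm[1] / 2, arena_cm[2] / 2)
  pull <- 0.12; noise_sd <- 0.35
  for (f in seq_len(n_frames)) {
    drift <- if (is.na(target[f, 1])) c(0, 0) else pull * (target[f, ] - pos)
    pos <- pos + drift + stats::rnorm(2, sd = noise_sd)
    # reflect at walls
    for (d in 1:2) {
      if (pos[d] < 0) pos[d] <- -pos[d]
      if (pos[d] > arena_cm[d]) pos[d] <- 2 * arena_cm[d] - pos[d]
      pos[d] <- min(max(pos[d], 0), arena_cm[d])
    }
    chest[f, ] <- pos
  }

  yaw <- (cumsum(stats::rnorm(n_frames, sd = 4))) %% 360
  pitch <- 40 * tanh(.ar1(n_frames, 0.98, 0.05))
  roll <- 40 * tanh(.ar1(n_frames, 0.98, 0.05))
  head_angles <- cbind(yaw = yaw, pitch = pitch, roll = roll)

  factors <- vapply(seq_len(n_factors), function(k) .ar1(n_frames, 0.97, 1),
                    numeric(n_frames))
  factors <- scale(factors, center = TRUE, scale = TRUE)
  if (coupling > 0) {
    speed <- c(0, sqrt(rowSums(diff(chest)^2))) * frame_rate
    prox <- -sqrt(colSums((t(chest) - ports["center", ])^2))
    drive <- cbind(as.numeric(scale(speed)), as.numeric(scale(prox)))
    for (k in seq_len(min(2L, n_factors)))
      factors[, k] <- sqrt(1 - coupling^2) * factors[, k] + coupling * drive[, k]
  }
  factors <- scale(factors, center = TRUE, scale = FALSE)

  load_v <- matrix(stats::rnorm(n_factors * n_components), n_factors)
  load_m <- matrix(stats::rnorm(n_factors * n_components), n_factors)
  video <- factors %*% load_v +
    matrix(stats::rnorm(n_frames * n_components, sd = 0.3), n_frames)
  motion <- factors %*% load_m +
    matrix(stats::rnorm(n_frames * n_components, sd = 0.3), n_frames)
  strip <- function(m) {
    m <- as.matrix(m)
    attr(m, "scaled:center") <- NULL; attr(m, "scaled:scale") <- NULL
    m
  }
  video <- strip(scale(video, center = TRUE, scale = FALSE))
  motion <- strip(scale(motion, center = TRUE, scale = FALSE))

  list(chest_xy = chest, head_angles = head_angles,
       video_svd = video, motion_svd = motion,
       latent = list(factors = strip(factors), loadings_video = load_v,
                     loadings_motion = load_m, coupling = coupling))
}
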