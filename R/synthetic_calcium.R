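#' Specification of a synthetic calcium-imaging movie
#'
#' Defaults follow the acquisition the generator emulates: 185 s at four
#' frames per second (740 frames), drug stimulus within the first 10 s,
#' fast-rising stimulus-locked transients. Amplitudes and noise are in
#' dF/F0 units; pixel intensity noise is `noise_sd` times the background
#' fluorescence level.
#'
#' @param n_responders,n_nonresponders soma counts (>= 0).
#' @param frame_rate frames per second.
#' @param duration record length in seconds.
#' @param stimulus_time stimulus onset in seconds, < duration.
#' @param transient_amplitude plateau dF/F0 of a responder transient.
#' @param transient_rise_tau rise time constant in seconds (calcium
#'   indicator transients rise on a sub-second scale).
#' @param noise_sd per-pixel Gaussian noise, dF/F0 units.
#' @param seed integer RNG seed.
#' @return object of class `calcium_movie_spec`.
#' @export
calcium_movie_spec <- function(n_responders = 10L, n_nonresponders = 10L,
                               frame_rate = 4, duration = 185,
                               stimulus_time = 10,
                               transient_amplitude = 1.0,
                               transient_rise_tau = 0.5,
                               noise_sd = 0.1, seed = 1L) {
  stopifnot(n_responders >= 0, n_nonresponders >= 0, frame_rate > 0,
            stimulus_time < duration, stimulus_time >= 0,
            transient_rise_tau > 0, noise_sd >= 0)
  structure(list(n_responders = as.integer(n_responders),
                 n_nonresponders = as.integer(n_nonresponders),
                 frame_rate = frame_rate, duration = duration,
                 stimulus_time = stimulus_time,
                 transient_amplitude = transient_amplitude,
                 transient_rise_tau = transient_rise_tau,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "calcium_movie_spec")
}

#' Synthesize a calcium-imaging movie with ground-truth responder labels
#'
#' Gaussian-profile somata (spatial sigma `soma_sigma` px, baseline contrast
#' `soma_contrast` above a flat background of `background_level` intensity
#' units) are placed on a jittered grid with a minimum separation of
#' 4 * `soma_sigma` pixels. Responder somata follow the baseline and then a
#' rising-exponential transient of plateau `transient_amplitude` starting at
#' the stimulus time; nonresponders stay at baseline. Independent Gaussian
#' noise of sd `noise_sd * background_level` is added to every pixel of
#' every frame.
#'
#' @param spec a [calcium_movie_spec()].
#' @param image_size image edge in pixels.
#' @param soma_sigma Gaussian soma radius parameter in pixels.
#' @param soma_contrast baseline soma brightness as a fraction of background.
#' @param background_level background fluorescence in intensity units.
#' @return list: `movie` (a [calcium_movie()]) and `truth` (data.frame with
#'   soma_id, y, x, is_responder).
#' @export
make_calcium_movie <- function(spec, image_size = 160L, soma_sigma = 6,
                               soma_contrast = 3, background_level = 100) {
  stopifnot(inherits(spec, "calcium_movie_spec"))
  n <- as.integer(image_size)
  n_somata <- spec$n_responders + spec$n_nonresponders
  sep <- ceiling(4 * soma_sigma)
  margin <- sep
  slots_per_side <- max(0L, floor((n - 2 * margin) / sep) + 1L)
  if (n_somata > slots_per_side^2) {
    stop("cannot place ", n_somata, " somata without overlap: only ",
         slots_per_side^2, " positions at a minimum separation of ", sep,
         " px in a ", n, "x", n, " field")
  }
  nt <- round(spec$duration * spec$frame_rate)

  with_seed(spec$seed, {
    slots <- expand.grid(
      y = margin + sep * seq(0L, slots_per_side - 1L),
      x = margin + sep * seq(0L, slots_per_side - 1L))
    pick <- sample.int(nrow(slots), n_somata)
    cy <- slots$y[pick] + stats::runif(n_somata, -2, 2)
    cx <- slots$x[pick] + stats::runif(n_somata, -2, 2)
    is_resp <- rep(c(TRUE, FALSE),
                   c(spec$n_responders, spec$n_nonresponders))
    is_resp <- sample(is_resp)

    # static baseline image: background plus every soma at baseline contrast
    profiles <- vector("list", n_somata)
    base_img <- matrix(background_level, n, n)
    for (i in seq_len(n_somata)) {
      g <- exp(-(outer((seq_len(n) - cy[i])^2, (seq_len(n) - cx[i])^2,
                       `+`)) / (2 * soma_sigma^2))
      profiles[[i]] <- g
      base_img <- base_img + background_level * soma_contrast * g
    }

    t_s <- (seq_len(nt) - 1L) / spec$frame_rate
    frames <- matrix(rep(as.vector(base_img), each = nt), nt, n * n)
    rise <- ifelse(t_s >= spec$stimulus_time,
                   1 - exp(-(t_s - spec$stimulus_time) /
                             spec$transient_rise_tau), 0)
    if (any(is_resp)) {
      resp_profile <- Reduce(`+`, profiles[is_resp])
      frames <- frames + (spec$transient_amplitude * background_level *
                            rise) %o% as.vector(resp_profile)
    }
    if (spec$noise_sd > 0) {
      frames <- frames + stats::rnorm(length(frames),
                                      sd = spec$noise_sd * background_level)
    }
    movie <- calcium_movie(array(frames, c(nt, n, n)), spec$frame_rate,
                           spec$stimulus_time, meta = list(seed = spec$seed))
    truth <- data.frame(soma_id = seq_len(n_somata), y = cy, x = cx,
                        is_responder = is_resp)
    list(movie = movie, truth = truth)
  })
}
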