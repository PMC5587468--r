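#' Generate the collar site table
#'
#' Lays out the measurement network the generator emulates: 4 automated
#' collars at the vertices of a 20 x 20 m square centred on the
#' micrometeorological tower, 27 manual collars spaced ~20 m across the plot
#' on two topographic features (plateau and slope), and 5 manual collars in a
#' detached canopy-gap cluster ~800 m north. Each collar carries structural
#' covariates (basal area within 5 m, canopy gap fraction, a one-off spatial
#' soil temperature snapshot) and a latent lognormal site multiplier u(x)
#' with coefficient of variation `config$site_cv` that scales its efflux.
#'
#' @param config a [sim_config()] object.
#' @param n_manual number of manual collars (last 5 form the gap cluster when
#'   `n_manual >= 10`).
#' @return data.frame of class `collar_sites`: `site_id`, `x`, `y` (m),
#'   `topo_class` (plateau/slope/gap), `basal_area_5m` (m2), `gap_fraction`,
#'   `t_spatial` (degC), `system` (automated/manual), `u` (site multiplier).
#' @export
make_collar_sites <- function(config, n_manual = config$n_manual) {
  set.seed(config$seed + 1L)
  sdlog <- sqrt(log(1 + config$site_cv^2))

  auto <- data.frame(
    site_id = sprintf("A%02d", 1:4),
    x = c(-10, 10, 10, -10), y = c(-10, -10, 10, 10),
    topo_class = "plateau", system = "automated"
  )

  n_gap <- if (n_manual >= 10) 5L else 0L
  n_plot <- n_manual - n_gap
  gx <- rep(seq(30, 130, by = 20), times = 5)
  gy <- rep(seq(-40, 40, by = 20), each = 6)
  keep <- seq_len(n_plot)
  man <- data.frame(
    site_id = sprintf("M%02d", seq_len(n_plot)),
    x = gx[keep] + stats::runif(n_plot, -2, 2),
    y = gy[keep] + stats::runif(n_plot, -2, 2),
    topo_class = ifelse(gx[keep] > 90, "slope", "plateau"),
    system = "manual"
  )
  sites <- rbind(auto, man)
  if (n_gap > 0) {
    gap <- data.frame(
      site_id = sprintf("G%02d", seq_len(n_gap)),
      x = stats::runif(n_gap, -10, 10),
      y = 820 + stats::runif(n_gap, -10, 10),
      topo_class = "gap", system = "manual"
    )
    sites <- rbind(sites, gap)
  }

  n <- nrow(sites)
  sites$basal_area_5m <- stats::rlnorm(n, meanlog = log(2.5), sdlog = 0.5)
  gf <- stats::rbeta(n, 2, 18)
  gf[sites$topo_class == "gap"] <- stats::rbeta(sum(sites$topo_class == "gap"),
                                                6, 14)
  sites$gap_fraction <- pmin(0.95, pmax(0.01, gf))
  sites$t_spatial <- 26 + stats::rnorm(n, 0, 0.3)
  sites$u <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  class(sites) <- c("collar_sites", "data.frame")
  sites
}
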