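#' Instantaneous whole-body muscle metabolic power
#'
#' Heat-rate energetics in the Anderson-Pandy tradition, with coefficients in
#' the coded rate table: per muscle, an activation/maintenance heat rate
#' proportional to estimated muscle mass and twitch composition
#' (`mass * (25 + 128 * fast_twitch_fraction) * a` W), a shortening heat rate
#' (`0.25 * F * |v_ce|` during shortening), and the positive mechanical work
#' rate (`-F * v_ce` during shortening; eccentric work is not credited).
#' Muscle mass is estimated as `F_max * l_opt * density / specific_tension`
#' with density 1059.7 kg/m^3 and specific tension 0.25 MPa. A constant basal
#' rate (default 1.2 W per kg of unloaded body mass) is always included.
#'
#' @param mtu_states list with numeric vectors `a` (activations), `v_ce`
#'   (fiber velocities, m/s, negative = shortening), and `force` (tendon
#'   forces, N), one entry per muscle.
#' @param tab a [mtu_table()] (rows recycled over both legs if `mtu_states`
#'   covers 16 muscles).
#' @param body_mass unloaded body mass (kg) for the basal term.
#' @param basal_rate_per_kg basal metabolic rate (W/kg of unloaded body mass).
#' @return a `metabolic_rates` list: `per_muscle` (W), `activation_maintenance`
#'   (W, per muscle), `basal` (W), and `total` (W).
#' @export
metabolic_power <- function(mtu_states, tab, body_mass = 80,
                            basal_rate_per_kg = 1.2) {
  a <- mtu_states$a
  v <- mtu_states$v_ce
  f <- mtu_states$force
  n <- length(a)
  if (length(v) != n || length(f) != n)
    stop("a, v_ce, force must have equal length")
  if (n %% nrow(tab) != 0)
    stop("number of muscle states must be a multiple of the table rows")
  reps <- n / nrow(tab)
  big <- tab[rep(seq_len(nrow(tab)), reps), ]
  per <- rg_metabolic_cpp(as.list(big), a, v, f)
  am <- rg_heat_am_cpp(as.list(big), a)
  basal <- basal_rate_per_kg * body_mass
  structure(list(per_muscle = setNames(per, big$name),
                 activation_maintenance = setNames(am, big$name),
                 basal = basal,
                 total = basal + sum(per)),
            class = "metabolic_rates")
}
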