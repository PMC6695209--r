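# Parameterization of the thin-film clot-core model.
#
# Units throughout: concentrations in uM, time in s, lengths in um.
# Config files may give the initial TF/FVIIa level in pM (tf_star_0_pM) and
# FXI in nM; both are converted to uM once, at load.

#' Linearized Michaelis-Menten rate coefficient
#'
#' With substrate held at its plasma level `S0`, the Michaelis-Menten rate
#' `kcat*E*S/(Km+S)` becomes first order in enzyme with coefficient
#' `alpha = kcat*S0/(Km+S0)` (units s^-1).
#'
#' @param kcat Turnover number (s^-1).
#' @param Km Michaelis constant (uM).
#' @param S0 Constant substrate concentration (uM).
#' @return Linearized rate coefficient (s^-1). Vectorized over its arguments.
#' @examples
#' compute_alpha(1.15, 0.24, 0.17) # FX activation by TF/FVIIa, ~0.48
#' compute_alpha(30, 0.3, 1.4)     # prothrombin activation, ~24.7
#' @export
compute_alpha <- function(kcat, Km, S0) {
  if (!all(is.finite(kcat), is.finite(Km), is.finite(S0)))
    stop("compute_alpha: inputs must be finite numbers", call. = FALSE)
  if (any(kcat < 0) || any(Km < 0) || any(S0 < 0))
    stop("compute_alpha: kcat, Km and S0 must be non-negative", call. = FALSE)
  if (any(Km + S0 <= 0))
    stop("compute_alpha: Km + S0 must be positive", call. = FALSE)
  kcat * S0 / (Km + S0)
}

#' Dissociation rate from equilibrium and association constants
#'
#' For reversible adsorption `IIa + site <-> IIa.site` with dissociation
#' constant `Kd` and association rate `kf`, the off-rate is `kr = kf*Kd`.
#'
#' @param Kd Dissociation constant (uM).
#' @param kf Association rate (uM^-1 s^-1).
#' @return Dissociation rate (s^-1). Vectorized.
#' @examples
#' compute_kr(2.8, 100) # E-domain site: 280 s^-1
#' compute_kr(0.1, 100) # gamma'-site: 10 s^-1
#' @export
compute_kr <- function(Kd, kf) {
  if (!all(is.finite(Kd), is.finite(kf)))
    stop("compute_kr: inputs must be finite numbers", call. = FALSE)
  if (any(Kd < 0) || any(kf < 0))
    stop("compute_kr: Kd and kf must be non-negative", call. = FALSE)
  kf * Kd
}

#' One reaction row of the linearized cascade
#'
#' @param id Reaction index, 1-7.
#' @param substrate,enzyme Names (documentation only).
#' @param S0 Plasma substrate level (uM).
#' @param kcat Turnover (s^-1).
#' @param Km Michaelis constant (uM).
#' @param eta Effectiveness factor in `[0, 1]` (actual rate over ideal
#'   transport-unlimited rate).
#' @return A one-row data.frame with the derived `alpha` column.
#' @export
reaction_spec <- function(id, substrate, enzyme, S0, kcat, Km, eta = 1) {
  stopifnot(length(id) == 1L, id %in% 1:7)
  if (S0 <= 0) stop("reaction_spec: S0 must be positive", call. = FALSE)
  if (Km <= 0) stop("reaction_spec: Km must be positive", call. = FALSE)
  if (kcat < 0) stop("reaction_spec: kcat must be non-negative", call. = FALSE)
  if (eta < 0 || eta > 1)
    stop("reaction_spec: eta must lie in [0, 1]", call. = FALSE)
  data.frame(id = as.integer(id), substrate = substrate, enzyme = enzyme,
             S0 = S0, kcat = kcat, Km = Km,
             alpha = compute_alpha(kcat, Km, S0), eta = eta,
             stringsAsFactors = FALSE)
}

#' One thrombin-binding site class on fibrin
#'
#' @param name "E" (weak E-domain site) or "gamma" (strong gamma'-chain site).
#' @param Kd Dissociation constant (uM).
#' @param kf Association rate (uM^-1 s^-1).
#' @param sites_per_monomer Binding sites per fibrin monomer.
#' @return A one-row data.frame with the derived `kr` column.
#' @export
binding_site <- function(name, Kd, kf, sites_per_monomer) {
  if (sites_per_monomer <= 0)
    stop("binding_site: sites_per_monomer must be positive", call. = FALSE)
  data.frame(name = name, Kd = Kd, kf = kf, kr = compute_kr(Kd, kf),
             sites_per_monomer = sites_per_monomer, stringsAsFactors = FALSE)
}

#' Clot-core geometry
#'
#' @param delta Core thickness (um).
#' @param porosity Void fraction of the core (platelet-free volume).
#' @param patch_length,patch_width Extent of the reactive patch (um).
#' @return List with derived `area` (um^2) and pore volume `v_pore` (um^3).
#' @export
core_geometry <- function(delta = 15, porosity = 0.5,
                          patch_length = 250, patch_width = 250) {
  if (porosity <= 0 || porosity >= 1)
    stop("core_geometry: porosity must lie strictly in (0, 1)", call. = FALSE)
  if (delta <= 0 || patch_length <= 0 || patch_width <= 0)
    stop("core_geometry: lengths must be positive", call. = FALSE)
  area <- patch_length * patch_width
  list(delta = delta, porosity = porosity,
       patch_length = patch_length, patch_width = patch_width,
       area = area, v_pore = area * delta * porosity)
}

#' Baseline parameterization of the thin-film cascade
#'
#' The seven linearized reactions (with effectiveness factors
#' eta = 1, 1, 1, 0.18, 0.05, 0.36, 1), the two thrombin-fibrin binding site
#' classes (E-domain: Kd 2.8 uM, 1.6 sites/monomer; gamma': Kd 0.1 uM, 0.3
#' sites/monomer; both with kf = 100 uM^-1 s^-1), the 15-um core geometry,
#' and the first-order loss rates: free-species escape half-life 2 s
#' (k_elute = ln2/2), protease inhibition half-life 60 s (k_i = ln2/60),
#' TF/FVIIa inhibition half-life 180 s (k_i_tf = ln2/180). The initial
#' TF/FVIIa complex in the core is 2.2 pM and 70% of eluted thrombin is
#' booked as thrombin-antithrombin (TAT).
#'
#' @return An object of class `clot_params`.
#' @examples
#' p <- default_parameters()
#' signif(p$reactions$alpha, 3)
#' @export
default_parameters <- function() {
  reactions <- rbind(
    reaction_spec(1, "FX",         "TF/FVIIa",   0.17,  1.15,   0.24, 1),
    reaction_spec(2, "FIX",        "TF/FVIIa",   0.09,  1.8,    0.42, 1),
    reaction_spec(3, "FX",         "FIXa/FVIIIa", 0.17, 8.2,    0.082, 1),
    reaction_spec(4, "FII",        "FXa/FVa",    1.4,   30,     0.3,  0.18),
    reaction_spec(5, "fibrinogen", "FIIa",       18,    80,     6.5,  0.05),
    reaction_spec(6, "FXI",        "FIIa",       0.031, 1.3e-4, 0.05, 0.36),
    reaction_spec(7, "FIX",        "FXIa",       0.09,  0.21,   0.2,  1))
  sites <- rbind(
    binding_site("E",     2.8, 100, 1.6),
    binding_site("gamma", 0.1, 100, 0.3))
  p <- list(
    reactions     = reactions,
    sites         = sites,
    geometry      = core_geometry(),
    tf_star_0     = 2.2e-6,          # uM (2.2 pM)
    k_elute       = log(2) / 2,      # s^-1, free IIa and FXIa escape
    k_i           = log(2) / 60,     # s^-1, protease inhibition
    k_i_tf        = log(2) / 180,    # s^-1, TF/FVIIa inhibition
    tat_fraction  = 0.7,             # share of eluted IIa captured as TAT
    reaction_mask = rep(1, 7),       # scenario on/off multipliers per reaction
    overrides     = character(0))
  class(p) <- "clot_params"
  validate_parameters(p)
}

#' Validate a `clot_params` object
#'
#' @param p A `clot_params` object.
#' @return `p`, invisibly unchanged, or an error naming the offending field.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "clot_params"))
  r <- p$reactions
  if (nrow(r) != 7L || !identical(r$id, 1:7))
    stop("parameters: expected reactions with ids 1..7", call. = FALSE)
  if (any(r$S0 <= 0)) stop("parameters: reaction S0 must be positive", call. = FALSE)
  if (any(r$Km <= 0)) stop("parameters: reaction Km must be positive", call. = FALSE)
  if (any(r$kcat < 0)) stop("parameters: reaction kcat must be non-negative", call. = FALSE)
  if (any(r$eta < 0 | r$eta > 1))
    stop("parameters: eta must lie in [0, 1]", call. = FALSE)
  if (max(abs(r$alpha - compute_alpha(r$kcat, r$Km, r$S0)) /
          pmax(r$alpha, .Machine$double.xmin)) > 1e-12)
    stop("parameters: alpha out of sync with kcat*S0/(Km+S0)", call. = FALSE)
  s <- p$sites
  if (nrow(s) != 2L || !setequal(s$name, c("E", "gamma")))
    stop("parameters: expected binding sites named 'E' and 'gamma'", call. = FALSE)
  if (any(s$Kd < 0) || any(s$kf < 0) || any(s$sites_per_monomer <= 0))
    stop("parameters: invalid binding site constants", call. = FALSE)
  if (max(abs(s$kr - s$kf * s$Kd) / pmax(s$kr, .Machine$double.xmin)) > 1e-12)
    stop("parameters: kr out of sync with kf*Kd", call. = FALSE)
  for (fld in c("tf_star_0", "k_elute", "k_i", "k_i_tf"))
    if (!is.numeric(p[[fld]]) || length(p[[fld]]) != 1L || p[[fld]] < 0)
      stop(sprintf("parameters: %s must be a single non-negative number", fld),
           call. = FALSE)
  if (p$tat_fraction < 0 || p$tat_fraction > 1)
    stop("parameters: tat_fraction must lie in [0, 1]", call. = FALSE)
  if (length(p$reaction_mask) != 7L || any(p$reaction_mask < 0))
    stop("parameters: reaction_mask must be 7 non-negative multipliers",
         call. = FALSE)
  invisible(p)
}

#' @export
print.clot_params <- function(x, ...) {
  cat("Thin-film clot-core parameters\n")
  cat(sprintf("  TF*0 = %.3g pM, escape t1/2 = %.3g s, inhibition t1/2 = %.3g s\n",
              x$tf_star_0 * 1e6, log(2) / x$k_elute, log(2) / x$k_i))
  cat("  reactions (alpha in s^-1):\n")
  print(x$reactions[, c("id", "substrate", "enzyme", "alpha", "eta")],
        row.names = FALSE)
  cat("  binding sites:\n")
  print(x$sites, row.names = FALSE)
  if (length(x$overrides))
    cat("  overrides:", paste(x$overrides, collapse = "; "), "\n")
  invisible(x)
}

# Recompute the derived columns after direct field edits.
rederive_parameters <- function(p) {
  p$reactions$alpha <- compute_alpha(p$reactions$kcat, p$reactions$Km,
                                     p$reactions$S0)
  p$sites$kr <- compute_kr(p$sites$Kd, p$sites$kf)
  g <- p$geometry
  p$geometry <- core_geometry(g$delta, g$porosity, g$patch_length,
                              g$patch_width)
  p
}

#' Load model parameters from a YAML config file
#'
#' User values are merged onto [default_parameters()]; the derived `alpha`
#' and `kr` columns are re-derived whenever `kcat`, `Km`, `S0`, `Kd` or `kf`
#' are overridden, and every override is recorded in the returned object's
#' `overrides` field. An empty file yields the defaults.
#'
#' Recognized top-level keys: `tf_star_0_pM`, `k_elute`, `escape_halflife_s`,
#' `k_i`, `k_i_tf`, `tat_fraction`, `geometry` (with `delta_um`, `porosity`,
#' `patch_length_um`, `patch_width_um`), `reactions` (list of entries keyed
#' by `id` with any of `kcat`, `Km`, `S0_uM`, `eta`), `sites` (list keyed by
#' `name` with any of `Kd_uM`, `kf`, `sites_per_monomer`).
#'
#' @param path Path to a YAML file.
#' @return A validated `clot_params` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("load_config: no such file: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  p <- default_parameters()
  note <- function(key, value)
    p$overrides <<- c(p$overrides, sprintf("%s=%s", key, format(value)))

  known <- c("tf_star_0_pM", "k_elute", "escape_halflife_s", "k_i", "k_i_tf",
             "tat_fraction", "geometry", "reactions", "sites")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop(sprintf("load_config: unknown key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  num1 <- function(x, key) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("load_config: '%s' must be a single finite number", key),
           call. = FALSE)
    x
  }
  if (!is.null(cfg$tf_star_0_pM)) {
    v <- num1(cfg$tf_star_0_pM, "tf_star_0_pM")
    if (v < 0) stop("load_config: 'tf_star_0_pM' must be non-negative", call. = FALSE)
    p$tf_star_0 <- v * 1e-6; note("tf_star_0_pM", v)
  }
  if (!is.null(cfg$k_elute) && !is.null(cfg$escape_halflife_s))
    stop("load_config: give either 'k_elute' or 'escape_halflife_s', not both",
         call. = FALSE)
  if (!is.null(cfg$k_elute)) {
    v <- num1(cfg$k_elute, "k_elute")
    if (v < 0) stop("load_config: 'k_elute' must be non-negative", call. = FALSE)
    p$k_elute <- v; note("k_elute", v)
  }
  if (!is.null(cfg$escape_halflife_s)) {
    v <- num1(cfg$escape_halflife_s, "escape_halflife_s")
    if (v <= 0) stop("load_config: 'escape_halflife_s' must be positive", call. = FALSE)
    p$k_elute <- log(2) / v; note("escape_halflife_s", v)
  }
  for (key in c("k_i", "k_i_tf")) if (!is.null(cfg[[key]])) {
    v <- num1(cfg[[key]], key)
    if (v < 0) stop(sprintf("load_config: '%s' must be non-negative", key), call. = FALSE)
    p[[key]] <- v; note(key, v)
  }
  if (!is.null(cfg$tat_fraction)) {
    v <- num1(cfg$tat_fraction, "tat_fraction")
    if (v < 0 || v > 1)
      stop("load_config: 'tat_fraction' must lie in [0, 1]", call. = FALSE)
    p$tat_fraction <- v; note("tat_fraction", v)
  }
  if (!is.null(cfg$geometry)) {
    g <- cfg$geometry
    gmap <- c(delta_um = "delta", porosity = "porosity",
              patch_length_um = "patch_length", patch_width_um = "patch_width")
    bad <- setdiff(names(g), names(gmap))
    if (length(bad))
      stop(sprintf("load_config: unknown geometry key(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    for (key in names(g)) {
      v <- num1(g[[key]], paste0("geometry$", key))
      p$geometry[[gmap[[key]]]] <- v
      note(paste0("geometry.", key), v)
    }
  }
  if (!is.null(cfg$reactions)) {
    rmap <- c(kcat = "kcat", Km = "Km", S0_uM = "S0", eta = "eta")
    for (entry in cfg$reactions) {
      if (is.null(entry$id) || !(entry$id %in% 1:7))
        stop("load_config: each reactions entry needs an 'id' in 1..7", call. = FALSE)
      i <- match(entry$id, p$reactions$id)
      bad <- setdiff(names(entry), c("id", names(rmap)))
      if (length(bad))
        stop(sprintf("load_config: unknown reaction key(s): %s",
                     paste(bad, collapse = ", ")), call. = FALSE)
      for (key in intersect(names(entry), names(rmap))) {
        v <- num1(entry[[key]], sprintf("reactions[id=%d]$%s", entry$id, key))
        if (key == "eta" && (v < 0 || v > 1))
          stop(sprintf("load_config: reactions[id=%d]$eta must lie in [0, 1]",
                       entry$id), call. = FALSE)
        if (key != "eta" && v < 0)
          stop(sprintf("load_config: reactions[id=%d]$%s must be non-negative",
                       entry$id, key), call. = FALSE)
        p$reactions[[rmap[[key]]]][i] <- v
        note(sprintf("reactions[%d].%s", entry$id, key), v)
      }
    }
  }
  if (!is.null(cfg$sites)) {
    smap <- c(Kd_uM = "Kd", kf = "kf", sites_per_monomer = "sites_per_monomer")
    for (entry in cfg$sites) {
      if (is.null(entry$name) || !(entry$name %in% c("E", "gamma")))
        stop("load_config: each sites entry needs name 'E' or 'gamma'", call. = FALSE)
      i <- match(entry$name, p$sites$name)
      bad <- setdiff(names(entry), c("name", names(smap)))
      if (length(bad))
        stop(sprintf("load_config: unknown site key(s): %s",
                     paste(bad, collapse = ", ")), call. = FALSE)
      for (key in intersect(names(entry), names(smap))) {
        v <- num1(entry[[key]], sprintf("sites[%s]$%s", entry$name, key))
        if (v < 0)
          stop(sprintf("load_config: sites[%s]$%s must be non-negative",
                       entry$name, key), call. = FALSE)
        p$sites[[smap[[key]]]][i] <- v
        note(sprintf("sites[%s].%s", entry$name, key), v)
      }
    }
  }
  validate_parameters(rederive_parameters(p))
}

#' Serialize parameters back to the config schema
#'
#' Writes a YAML file that [load_config()] reads back to an identical
#' parameter set (round-trip identity).
#'
#' @param p A `clot_params` object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(p, path) {
  validate_parameters(p)
  cfg <- list(
    tf_star_0_pM = p$tf_star_0 * 1e6,
    k_elute = p$k_elute, k_i = p$k_i, k_i_tf = p$k_i_tf,
    tat_fraction = p$tat_fraction,
    geometry = list(delta_um = p$geometry$delta,
                    porosity = p$geometry$porosity,
                    patch_length_um = p$geometry$patch_length,
                    patch_width_um = p$geometry$patch_width),
    reactions = lapply(seq_len(nrow(p$reactions)), function(i)
      list(id = p$reactions$id[i], kcat = p$reactions$kcat[i],
           Km = p$reactions$Km[i], S0_uM = p$reactions$S0[i],
           eta = p$reactions$eta[i])),
    sites = lapply(seq_len(nrow(p$sites)), function(i)
      list(name = p$sites$name[i], Kd_uM = p$sites$Kd[i],
           kf = p$sites$kf[i],
           sites_per_monomer = p$sites$sites_per_monomer[i])))
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Export the fully resolved parameter set as JSON
#'
#' Intended for provenance sidecars next to result files.
#'
#' @param p A `clot_params` object.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
export_params_json <- function(p, path = NULL) {
  validate_parameters(p)
  x <- unclass(p)
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Homogenize a TF surface density over the core pore volume
#'
#' Converts a surface density of TF molecules (with an active TF/FVIIa
#' fraction) into a volumetric concentration over the core pore space,
#' `fraction * density * area / (N_A * v_pore)`. With the default geometry
#' (15 um core, porosity 0.5) and 1 molecule/um^2 at 1% active this gives
#' 2.2e-6 uM (2.2 pM), the baseline TF* of [default_parameters()]; the
#' helper documents that consistency and supports alternative surface
#' densities or core geometries.
#'
#' @param density_per_um2 TF surface density (molecules/um^2).
#' @param fraction_active Fraction present as active TF/FVIIa.
#' @param geometry A [core_geometry()] list.
#' @return Concentration in uM.
#' @export
tf_surface_to_concentration <- function(density_per_um2 = 1,
                                        fraction_active = 0.01,
                                        geometry = core_geometry()) {
  avogadro <- 6.02214076e23
  molecules <- fraction_active * density_per_um2 * geometry$area
  moles <- molecules / avogadro
  litres <- geometry$v_pore * 1e-15   # um^3 -> L
  moles / litres * 1e6                # mol/L -> uM
}
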