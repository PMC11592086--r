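# Plain-text configuration I/O (YAML) for muscle, controller and
# scenario descriptions, used by the command-line tools.

#' Write / read the muscle + Hill parameter configuration
#'
#' YAML key-value file holding [huxley_parameters()], the Hill constants
#' and the numerical settings of the reduction.
#'
#' @param muscle [huxley_parameters()].
#' @param hill [hill_parameters()].
#' @param path file path.
#' @param n_grid,order,dt numerical settings stored alongside.
#' @export
write_muscle_config <- function(muscle, hill, path, n_grid = 64,
                                order = 3, dt = 1e-3) {
  yaml::write_yaml(list(
    gamma = muscle$gamma, f1 = muscle$f1, g1 = muscle$g1, g2 = muscle$g2,
    x_min = muscle$x_min, x_max = muscle$x_max,
    force_scale = muscle$force_scale,
    F0 = hill$F0, Fa = hill$Fa, vb = hill$vb,
    n_grid = n_grid, order = order, dt = dt), path)
  invisible(path)
}

#' @rdname write_muscle_config
#' @return `read_muscle_config()` returns a list with elements `muscle`,
#'   `hill`, `n_grid`, `order`, `dt`.
#' @export
read_muscle_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("F0", "Fa", "vb")
  if (!all(need %in% names(y)))
    stop("muscle config must provide F0, Fa, vb", call. = FALSE)
  muscle <- huxley_parameters(
    gamma = y$gamma %||% -3, f1 = y$f1 %||% 5, g1 = y$g1 %||% 50,
    g2 = y$g2 %||% 100, x_min = y$x_min %||% -1, x_max = y$x_max %||% 2,
    force_scale = y$force_scale)
  list(muscle = muscle,
       hill = hill_parameters(y$F0, y$Fa, y$vb),
       n_grid = y$n_grid %||% 64, order = y$order %||% 3,
       dt = y$dt %||% 1e-3)
}

#' Read an activation profile from YAML
#'
#' Expects keys `times` and `levels` (parallel lists).
#'
#' @param path file path.
#' @export
read_activation_profile <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$times) || is.null(y$levels))
    stop("profile YAML must provide `times` and `levels`", call. = FALSE)
  activation_profile(unlist(y$times), unlist(y$levels))
}

#' Read a grasp scenario from YAML
#'
#' Top-level keys: `object` (`stiffness`, plus either
#' `surface_position` or `theta_touch`, optional `label`), `profile`
#' (`times`, `levels`), optional `seed`, optional `muscle_config` (path
#' to a [write_muscle_config()] file, resolved relative to the scenario
#' file) and optional `controller` overrides for
#' [controller_config()].
#'
#' @param path file path.
#' @return a [grasp_scenario()].
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$object) || is.null(y$profile))
    stop("scenario YAML must provide `object` and `profile`", call. = FALSE)
  mc <- if (!is.null(y$muscle_config)) {
    p <- y$muscle_config
    if (!file.exists(p)) p <- file.path(dirname(path), y$muscle_config)
    read_muscle_config(p)
  } else list(muscle = huxley_parameters(), hill = hill_parameters())
  links <- finger_links()
  map <- linear_coupling()
  geom <- contact_geometry()
  surf <- if (!is.null(y$object$surface_position)) y$object$surface_position
  else {
    th <- y$object$theta_touch %||% 0.5
    sum(c(0, 1) * contact_point(coupled_configuration(th, map),
                                geom, links)$p)
  }
  ctrl <- do.call(controller_config, y$controller %||% list())
  grasp_scenario(
    object = object_model(surf, y$object$stiffness,
                          y$object$label %||% "object"),
    profile = activation_profile(unlist(y$profile$times),
                                 unlist(y$profile$levels)),
    seed = y$seed %||% 1,
    muscle = mc$muscle, hill = mc$hill,
    links = links, map = map, geom = geom, control = ctrl,
    label = y$object$label %||% basename(path))
}
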