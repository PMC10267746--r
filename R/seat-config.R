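#' Seat configuration
#'
#' Bundle of the geometric and loading parameters describing one seat
#' condition: seat-pan angle (SPA, tilt of the pan from horizontal), seat-pan
#' to backrest angle (SP2BA, included angle between pan and backrest planes),
#' subject weight force, and friction-coefficient metadata for the seat and
#' footrest contacts.
#'
#' @param spa_deg Seat-pan angle from horizontal, degrees; `0 <= spa_deg < 90`.
#' @param sp2ba_deg Seat-pan to backrest angle, degrees; `90 < sp2ba_deg < 180`.
#' @param body_weight_N Subject weight force in newtons, `> 0`.
#' @param cof_seat,cof_foot Coefficients of friction carried as metadata
#'   (seat-pan/backrest contact and foot-support contact).
#' @param label Optional condition label, e.g. `"SPA5"`.
#'
#' @return An object of class `seat_config`.
#' @examples
#' cfg <- seat_config(spa_deg = 5, sp2ba_deg = 100, body_weight_N = 784.8)
#' surface_tilt_angle(cfg, "SB")
#' @export
seat_config <- function(spa_deg, sp2ba_deg = 100, body_weight_N,
                        cof_seat = 0.1, cof_foot = 0.4, label = NULL) {
  stopifnot(is.numeric(spa_deg), length(spa_deg) == 1, is.finite(spa_deg),
            is.numeric(sp2ba_deg), length(sp2ba_deg) == 1, is.finite(sp2ba_deg),
            is.numeric(body_weight_N), length(body_weight_N) == 1)
  if (spa_deg < 0 || spa_deg >= 90)
    stop("`spa_deg` must satisfy 0 <= spa_deg < 90, got ", spa_deg)
  if (sp2ba_deg <= 90 || sp2ba_deg >= 180)
    stop("`sp2ba_deg` must satisfy 90 < sp2ba_deg < 180, got ", sp2ba_deg)
  if (!is.finite(body_weight_N) || body_weight_N <= 0)
    stop("`body_weight_N` must be a positive force in N")
  structure(
    list(spa_deg = spa_deg, sp2ba_deg = sp2ba_deg,
         body_weight_N = body_weight_N,
         cof_seat = cof_seat, cof_foot = cof_foot,
         label = if (is.null(label)) sprintf("SPA%g", spa_deg) else label),
    class = "seat_config")
}

#' @export
print.seat_config <- function(x, ...) {
  cat(sprintf(
    "<seat_config %s>  SPA %g deg, SP2BA %g deg, W %.1f N (COF seat %.2f, foot %.2f)\n",
    x$label, x$spa_deg, x$sp2ba_deg, x$body_weight_N, x$cof_seat, x$cof_foot))
  invisible(x)
}

#' Contact surfaces
#'
#' The three load-bearing surfaces of the rig: seat back (`"SB"`), seat pan
#' (`"SP"`) and foot support (`"FS"`).
#' @keywords internal
surface_tags <- c("SB", "SP", "FS")

#' Tilt of a contact surface from horizontal
#'
#' The local frame of each surface is the global frame rotated about the
#' lateral y-axis by the surface tilt: the seat pan is tilted by SPA, the
#' backrest by `SPA + SP2BA - 90` (its tilt from *vertical*, so that the
#' local x-axis lies in the backrest plane), and the foot support is
#' horizontal.
#'
#' @param config A [seat_config()].
#' @param surface One of `"SB"`, `"SP"`, `"FS"`.
#' @return Tilt angle in degrees.
#' @export
surface_tilt_angle <- function(config, surface) {
  stopifnot(inherits(config, "seat_config"))
  if (!(is.character(surface) && length(surface) == 1 && surface %in% surface_tags))
    stop("unknown surface tag ", deparse(surface),
         "; expected one of ", paste(surface_tags, collapse = ", "))
  switch(surface,
         SP = config$spa_deg,
         SB = config$spa_deg + config$sp2ba_deg - 90,
         FS = 0)
}
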