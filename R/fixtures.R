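# Small worked examples used throughout the documentation and tests:
# a three-leaf tree, the smallest binary level-1 network with one cycle, a
# network with two hybrids in one block, a network with a shortcut, and the
# clustering systems of the figures discussed in the vignette.

#' Catalogue of small example networks and clustering systems
#'
#' Returns a named list:
#' \describe{
#'   \item{F_T3}{tree on three taxa: `r -> a, r -> 3, a -> 1, a -> 2`}
#'   \item{F_D1}{binary level-1 network with one 4-cycle:
#'     `r -> u, r -> v, u -> y, v -> z, u -> h, v -> h, h -> x`}
#'   \item{F_P1}{network whose single block contains two hybrids
#'     (`h1`, `h2`, both children of `a` and `b`)}
#'   \item{F_SC}{network with shortcut `(r, h)`:
#'     `r -> u, r -> h, u -> h, u -> y, h -> x`}
#'   \item{F_CSA}{clustering system `{{a},{b},{a,b}}`}
#'   \item{F_CS11}{system on `{w,x,y,z}` that is not closed
#'     (`{w,x,y}` and `{x,y,z}` overlap but `{x,y}` is missing)}
#'   \item{F_CS12}{the ten-cluster system on `{x,y,z,v}` whose cluster
#'     network is not tree-based}
#'   \item{F_CS_ALT3}{`{{1},{2},{3},{2,3},{1,2,3}}`}
#' }
#'
#' @return named list of `phynet` and `clustsys` objects
#' @export
fixtures <- function() {
  list(
    F_T3 = build_network(rbind(c("r", "a"), c("r", "3"),
                               c("a", "1"), c("a", "2"))),
    F_D1 = build_network(rbind(c("r", "u"), c("r", "v"), c("u", "y"),
                               c("v", "z"), c("u", "h"), c("v", "h"),
                               c("h", "x"))),
    F_P1 = build_network(rbind(c("r", "a"), c("r", "b"),
                               c("a", "h1"), c("b", "h1"),
                               c("a", "h2"), c("b", "h2"),
                               c("h1", "x"), c("h2", "y"))),
    F_SC = build_network(rbind(c("r", "u"), c("r", "h"), c("u", "h"),
                               c("u", "y"), c("h", "x"))),
    F_CSA = clustsys(list("a", "b", c("a", "b"))),
    F_CS11 = clustsys(list("w", "x", "y", "z",
                           c("w", "x", "y"), c("x", "y", "z"),
                           c("w", "x", "y", "z"))),
    F_CS12 = clustsys(list("x", "y", "z", "v",
                           c("x", "y"), c("x", "z"), c("x", "v"),
                           c("y", "z"), c("y", "v"),
                           c("x", "y", "z", "v"))),
    F_CS_ALT3 = clustsys(list("1", "2", "3", c("2", "3"), c("1", "2", "3")))
  )
}
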