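#' A small hypothetical metabolic network
#'
#' The nine-compound, three-reaction, two-enzyme network used throughout
#' the documentation and tests: sources `C1`, `C3`, `C6`; reaction `R1`
#' turns `C1` and `C7` into `C2` under enzyme `E2`; `R2` turns `C2` and
#' `C3` into `C4`, `C5` and `C7` under `E1`; `R3` turns `C6` into `C7`,
#' `C8` and `C9` under `E1`.  The compounds `C2`, `R2`, `C7`, `R1` form a
#' cycle, which makes the network a compact exercise of every semantic
#' subtlety the package handles: with target `C5`, inhibiting `E2` stops
#' the target at damage 2 (`C2` and `C4` are lost, while `C7` survives via
#' `R3`), whereas inhibiting `E1` costs damage 5 -- so `{E2}` is the
#' unique optimal single-enzyme answer.
#'
#' The same network ships as a parseable file under
#' `system.file("extdata", "demo.net", package = "eciopt")`.
#'
#' @return `demo_network()` a `metabolic_network`; `demo_instance()` the
#'   corresponding `eci_instance` with target `C5`.
#' @examples
#' solve_eci(demo_instance())
#' @export
demo_network <- function() {
  metabolic_network(
    compounds = paste0("C", 1:9),
    reactions = list(
      list(id = "R1", inputs = c("C1", "C7"), enzymes = "E2",
           products = "C2"),
      list(id = "R2", inputs = c("C2", "C3"), enzymes = "E1",
           products = c("C4", "C5", "C7")),
      list(id = "R3", inputs = "C6", enzymes = "E1",
           products = c("C7", "C8", "C9"))),
    enzymes = c("E1", "E2"))
}

#' @rdname demo_network
#' @export
demo_instance <- function() {
  eci_instance(demo_network(), "C5")
}
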