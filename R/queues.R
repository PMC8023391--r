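#' Spike queues with axonal delays
#'
#' Dendrites and axons are passive here: their only electrical effect is a
#' transmission delay, so every synaptic pathway is a queue of delivery
#' times. `deliver_spike` inserts one spike (delivery = emission + delay)
#' keeping the queue sorted; `pop_due` consumes every spike due at the
#' current step. Delays must be at least one time step, which guarantees a
#' spike can never be consumed in its emission step.
#'
#' @param queue numeric vector of pending delivery times (ms), sorted.
#' @param emission_time spike emission time (ms).
#' @param delay pathway delay (ms), >= the simulation step.
#' @return `deliver_spike`: the updated queue. `pop_due`: list with `due`
#'   (times consumed) and `queue` (remainder).
#' @export
deliver_spike <- function(queue, emission_time, delay) {
  stopifnot(delay > 0)
  t_del <- emission_time + delay
  pos <- findInterval(t_del, queue)
  append(queue, t_del, after = pos)
}

#' @rdname deliver_spike
#' @param t current time (ms).
#' @param dt step width (ms): spikes with `t <= delivery < t + dt` are due.
#' @export
pop_due <- function(queue, t, dt) {
  due <- queue >= t - 1e-9 & queue < t + dt - 1e-9
  list(due = queue[due], queue = queue[!due])
}

#' Gap-junction currents between Golgi cells
#'
#' `I_gap(i) = sum_j g_gap (Vm_i - Vm_j)` over the gap-junction partners
#' `j` of cell `i`; by construction the matrix is symmetric so the total
#' over a coupled pair is zero, and all currents vanish when the
#' potentials are equal. In the network loop the currents are computed
#' from the potentials of the previous step.
#'
#' @param vm vector of Golgi membrane potentials (mV).
#' @param gap_junction symmetric `gl_adj` (Golgi -> Golgi).
#' @param g_gap junction conductance (nS).
#' @return per-cell gap current (pA, outward positive).
#' @export
gap_currents <- function(vm, gap_junction, g_gap) {
  stopifnot(inherits(gap_junction, "gl_adj"),
            length(vm) == gap_junction$n_src)
  lens <- diff(gap_junction$ptr)
  src <- rep.int(seq_along(vm), lens)
  contrib <- g_gap * (vm[src] - vm[gap_junction$targets])
  out <- numeric(length(vm))
  acc <- tapply(contrib, src, sum)
  out[as.integer(names(acc))] <- acc
  out
}
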