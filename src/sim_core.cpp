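#include <Rcpp.h>
using namespace Rcpp;

// Elastic recoil pressure (cmH2O) at lung volume v, measured in mL above the
// relaxation volume.  For a linear system c_below holds Crs and the bilinear
// branch is unused.  The bilinear law switches elastance at the volume where
// the static recoil equals the lower inflection point (LIP).
static inline double pel(double v, bool bilinear, double c_below, double c_above,
                         double lip) {
  if (!bilinear) return v / c_below;
  double v_lip = c_below * lip;
  if (v <= v_lip) return v / c_below;
  return lip + (v - v_lip) / c_above;
}

static inline double pel_inv(double p, bool bilinear, double c_below,
                             double c_above, double lip) {
  if (!bilinear) return p * c_below;
  if (p <= lip) return p * c_below;
  return c_below * lip + (p - lip) * c_above;
}

// Advance the open-airway Y-piece pressure over a substep h with delivered
// flow q (L/s).  The pressure relaxes exponentially (time constant
// Rrs*Ccirc/1000) toward the quasi-steady value pel(valv)+Rrs*q, which keeps
// the update stable for arbitrarily small circuit compliances; the lung
// volume increment is taken from volume conservation (delivered minus what
// the circuit stored), so delivered = circuit + lung holds to rounding.
static inline void step_open(double& paw, double& valv, double q, double h,
                             double rrs, double ccirc, bool bilinear,
                             double c_below, double c_above, double lip) {
  double target = pel(valv, bilinear, c_below, c_above, lip) + rrs * q;
  double tau = rrs * ccirc / 1000.0;
  double a = std::exp(-h / tau);
  double paw_new = target + (paw - target) * a;
  double dvcirc = ccirc * (paw_new - paw);
  valv += 1000.0 * q * h - dvcirc;
  paw = paw_new;
}

// [[Rcpp::export]]
List sim_core(double rrs, bool bilinear, double c_below, double c_above,
              double lip, bool has_aop, double aop, double ccirc,
              double q_insp, double vt, double peep, double pause_s,
              double cycle_s, double r_exp, double dt, int n_cycles,
              double fs) {
  const int steps_per_cycle = (int)std::lround(cycle_s / dt);
  const int insp_steps = (int)std::lround(vt / (q_insp * 1000.0) / dt);
  const int pause_steps = (int)std::lround(pause_s / dt);
  const int rec_every = (int)std::lround(1.0 / (fs * dt));
  const int total_steps = steps_per_cycle * n_cycles;
  const int n_out = total_steps / rec_every;

  NumericVector t_out(n_out), flow_out(n_out), paw_out(n_out), valv_out(n_out);
  IntegerVector cycle_out(n_out);

  // Steady end-expiratory state: circuit at set PEEP; alveoli either
  // equilibrated at PEEP or trapped at the airway opening pressure.
  bool closed0 = has_aop && (peep < aop);
  double paw = peep;
  double valv = pel_inv(closed0 ? aop : peep, bilinear, c_below, c_above, lip);
  bool open_aw = !closed0;

  int i_out = 0;
  for (int k = 0; k < total_steps; ++k) {
    int ls = k % steps_per_cycle;  // local step within cycle
    bool in_insp = ls < insp_steps;
    bool in_pause = !in_insp && ls < insp_steps + pause_steps;

    double rec_flow;
    if (in_insp) {
      rec_flow = q_insp;
    } else if (in_pause) {
      rec_flow = 0.0;
    } else {
      if (open_aw) {
        double dp = pel(valv, bilinear, c_below, c_above, lip) - peep;
        rec_flow = dp > 0.0 ? -dp / r_exp : 0.0;
      } else {
        rec_flow = 0.0;
      }
    }

    if (k % rec_every == 0) {
      t_out[i_out] = k * dt;
      flow_out[i_out] = rec_flow;
      paw_out[i_out] = paw;
      valv_out[i_out] = valv;
      cycle_out[i_out] = k / steps_per_cycle + 1;
      ++i_out;
    }

    if (in_insp) {
      if (!open_aw && paw >= aop) open_aw = true;
      if (!open_aw) {
        // airway closed: delivered gas only compresses in the circuit
        double dpaw = 1000.0 * q_insp / ccirc * dt;
        if (paw + dpaw >= aop) {
          // sub-step to the exact opening instant, then integrate the rest
          double f = (aop - paw) / dpaw;
          paw = aop;
          open_aw = true;
          if (f < 1.0)
            step_open(paw, valv, q_insp, (1.0 - f) * dt, rrs, ccirc, bilinear,
                      c_below, c_above, lip);
        } else {
          paw += dpaw;
        }
      } else {
        step_open(paw, valv, q_insp, dt, rrs, ccirc, bilinear, c_below,
                  c_above, lip);
      }
    } else if (in_pause) {
      if (open_aw)
        step_open(paw, valv, 0.0, dt, rrs, ccirc, bilinear, c_below, c_above,
                  lip);
      // closed airway during occlusion: nothing moves
    } else {
      // expiration: exhalation valve holds the Y piece at set PEEP; the lung
      // empties through the expiratory pathway resistance
      if (open_aw) {
        double palv = pel(valv, bilinear, c_below, c_above, lip);
        double qexp = (palv - peep) / r_exp;
        if (qexp > 0.0) {
          valv -= 1000.0 * qexp * dt;
          double v_eq = pel_inv(peep, bilinear, c_below, c_above, lip);
          if (valv < v_eq) valv = v_eq;
          if (has_aop && peep < aop &&
              pel(valv, bilinear, c_below, c_above, lip) <= aop) {
            valv = pel_inv(aop, bilinear, c_below, c_above, lip);
            open_aw = false;
          }
        }
      }
      paw = peep;
    }
  }

  return List::create(_["t"] = t_out, _["flow"] = flow_out,
                      _["paw"] = paw_out, _["valv"] = valv_out,
                      _["cycle"] = cycle_out,
                      _["steps_per_cycle"] = steps_per_cycle,
                      _["insp_steps"] = insp_steps);
}
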