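#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the clonal (adaptive-dynamics) SI system.
//
// State: S[i], R[i] uninfected densities over the general-resistance grid q,
// plus the two infected pools Ie (endemic) and If (foreign).  Infected hosts
// are sterile and die at mu like everyone else.  `cost` is the precomputed
// fecundity cost 1-(1-q)^theta per bin.  freq_mode switches the transmission
// terms between I/N (frequency-dependent) and I (density-dependent).
//
// Non-negativity is enforced by projection after every step; compartments are
// never clamped to zero here (that happens once, at the end of an
// equilibration phase, at the R level).  State is copied into local buffers
// so the loop runs on raw doubles.
// [[Rcpp::export]]
List clonal_euler_cpp(NumericVector S0, NumericVector R0, double Ie0, double If0,
                      NumericVector q, NumericVector cost,
                      double b, double mu, double gamma,
                      double be, double bf, double r, double cr,
                      bool freq_mode, double dt, int nsteps, int record_every) {
  const int n = S0.size();
  std::vector<double> S(S0.begin(), S0.end()), R(R0.begin(), R0.end());
  std::vector<double> qv(q.begin(), q.end()), cv(cost.begin(), cost.end());
  std::vector<double> dS(n), dR(n);
  double Ie = Ie0, If = If0;

  const int nrec = (record_every > 0) ? (nsteps / record_every + 1) : 0;
  NumericMatrix traj(nrec, 5); // t, sum(S), sum(R), Ie, If
  int irec = 0;

  for (int step = 0; step <= nsteps; ++step) {
    if (record_every > 0 && step % record_every == 0 && irec < nrec) {
      double sS = 0.0, sR = 0.0;
      for (int i = 0; i < n; ++i) { sS += S[i]; sR += R[i]; }
      traj(irec, 0) = step * dt;
      traj(irec, 1) = sS; traj(irec, 2) = sR;
      traj(irec, 3) = Ie; traj(irec, 4) = If;
      ++irec;
    }
    if (step == nsteps) break;

    double N = Ie + If;
    for (int i = 0; i < n; ++i) N += S[i] + R[i];

    if (N <= 0.0) continue; // identically-zero state is a fixed point

    const double Nd = freq_mode ? N : 1.0;

    double force_e = 0.0, force_f = 0.0; // summed infection terms in dIe, dIf
    for (int i = 0; i < n; ++i) {
      const double oq = 1.0 - qv[i];
      force_e += oq * (S[i] + (1.0 - r) * R[i]);
      force_f += oq * (S[i] + R[i]);
    }
    const double dIe = Ie * (be * force_e / Nd - mu);
    const double dIf = If * (bf * force_f / Nd - mu);

    const double press_e = (be * Ie + bf * If) / Nd;
    const double press_r = ((1.0 - r) * be * Ie + bf * If) / Nd;
    const double gS = b - mu - gamma * N;
    const double gR = gS - cr;
    for (int i = 0; i < n; ++i) {
      const double oq = 1.0 - qv[i];
      dS[i] = S[i] * (gS - cv[i] - oq * press_e);
      dR[i] = R[i] * (gR - cv[i] - oq * press_r);
    }

    if (!std::isfinite(dIe) || !std::isfinite(dIf))
      stop("non-finite derivative in infected pool at t=%f", step * dt);

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(dS[i]) || !std::isfinite(dR[i]))
        stop("non-finite derivative in host bin %d at t=%f", i + 1, step * dt);
      S[i] += dt * dS[i]; if (S[i] < 0.0) S[i] = 0.0;
      R[i] += dt * dR[i]; if (R[i] < 0.0) R[i] = 0.0;
    }
    Ie += dt * dIe; if (Ie < 0.0) Ie = 0.0;
    If += dt * dIf; if (If < 0.0) If = 0.0;
  }

  return List::create(_["S"] = NumericVector(S.begin(), S.end()),
                      _["R"] = NumericVector(R.begin(), R.end()),
                      _["I_e"] = Ie, _["I_f"] = If,
                      _["trajectory"] = traj);
}

// Forward-Euler integration of the two-locus four-genotype recombination
// model.  U holds the four uninfected genotype densities in the fixed order
// QpS, QpR, QmS, QmR.  M is the 16x4 mating matrix: row 4*m+f gives the
// offspring-genotype distribution for mother m crossed with father f.
// Births of genotype g: sum over parent pairs of
//   (b - cost[mother]) * U[mother] * (U[father]/U_tot) * M[mother,father -> g],
// i.e. fecundity (and its costs) belongs to the mother, fathers are drawn
// from the uninfected pollen pool, and infected plants are fully sterile.
// [[Rcpp::export]]
List recomb_euler_cpp(NumericVector U0, double Ie0, double If0,
                      NumericVector qg, LogicalVector isR, NumericVector cost,
                      NumericMatrix M,
                      double b, double mu, double gamma,
                      double be, double bf, double r,
                      bool freq_mode, double dt, int nsteps, int record_every) {
  double U[4] = {U0[0], U0[1], U0[2], U0[3]};
  double qv[4], cv[4], spec[4], Mm[16][4];
  for (int g = 0; g < 4; ++g) {
    qv[g] = qg[g]; cv[g] = cost[g];
    spec[g] = isR[g] ? (1.0 - r) : 1.0;
  }
  for (int row = 0; row < 16; ++row)
    for (int g = 0; g < 4; ++g) Mm[row][g] = M(row, g);
  double Ie = Ie0, If = If0;

  const int nrec = (record_every > 0) ? (nsteps / record_every + 1) : 0;
  NumericMatrix traj(nrec, 7); // t, U1..U4, Ie, If
  int irec = 0;

  double Bg[4], dU[4];

  for (int step = 0; step <= nsteps; ++step) {
    if (record_every > 0 && step % record_every == 0 && irec < nrec) {
      traj(irec, 0) = step * dt;
      for (int g = 0; g < 4; ++g) traj(irec, 1 + g) = U[g];
      traj(irec, 5) = Ie; traj(irec, 6) = If;
      ++irec;
    }
    if (step == nsteps) break;

    const double Ut = U[0] + U[1] + U[2] + U[3];
    const double N = Ut + Ie + If;
    if (N <= 0.0) continue;
    const double Nd = freq_mode ? N : 1.0;

    for (int g = 0; g < 4; ++g) Bg[g] = 0.0;
    if (Ut > 0.0) {
      for (int m = 0; m < 4; ++m) {
        if (U[m] <= 0.0) continue;
        const double fec = (b - cv[m]) * U[m];
        for (int f = 0; f < 4; ++f) {
          if (U[f] <= 0.0) continue;
          const double w = fec * U[f] / Ut;
          const double* row = Mm[4 * m + f];
          for (int g = 0; g < 4; ++g) Bg[g] += w * row[g];
        }
      }
    }

    double force_e = 0.0, force_f = 0.0;
    for (int g = 0; g < 4; ++g) {
      const double oq = 1.0 - qv[g];
      force_e += oq * spec[g] * U[g];
      force_f += oq * U[g];
    }
    const double dIe = Ie * (be * force_e / Nd - mu);
    const double dIf = If * (bf * force_f / Nd - mu);

    for (int g = 0; g < 4; ++g) {
      const double oq = 1.0 - qv[g];
      dU[g] = Bg[g] - U[g] * (mu + gamma * N)
            - U[g] * oq * (spec[g] * be * Ie + bf * If) / Nd;
      if (!std::isfinite(dU[g]))
        stop("non-finite derivative in genotype %d at t=%f", g + 1, step * dt);
    }
    if (!std::isfinite(dIe) || !std::isfinite(dIf))
      stop("non-finite derivative in infected pool at t=%f", step * dt);

    for (int g = 0; g < 4; ++g) {
      U[g] += dt * dU[g]; if (U[g] < 0.0) U[g] = 0.0;
    }
    Ie += dt * dIe; if (Ie < 0.0) Ie = 0.0;
    If += dt * dIf; if (If < 0.0) If = 0.0;
  }

  return List::create(_["U"] = NumericVector(U, U + 4),
                      _["I_e"] = Ie, _["I_f"] = If,
                      _["trajectory"] = traj);
}
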