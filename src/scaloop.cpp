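// Statistical catch-at-age estimation model.
//
// Age-structured population recursion matching the operating model exactly:
// unfished equilibrium start, start-of-year spawning, Beverton-Holt
// recruitment with lognormal deviations and per-year bias-adjustment
// factors b_y, logistic selectivity, and Baranov catch. The model conditions
// on observed catch biomass: per-year fishing mortality is solved by Newton
// iteration inside the template (differentiated through by AD), so F carries
// no free parameters. Likelihood: lognormal survey index, multinomial age
// and length compositions, Normal penalty on recruitment deviations.
#define TMB_LIB_INIT R_init_scaloop
#include <TMB.hpp>

template <class Type>
Type objective_function<Type>::operator()()
{
  DATA_VECTOR(ages);          // model ages 0..A (A = plus group)
  DATA_VECTOR(w_a);           // weight-at-age (kg)
  DATA_VECTOR(mat_a);         // maturity-at-age (age 0 = 0)
  DATA_MATRIX(alk);           // age-length transition, nbins x nages
  DATA_VECTOR(b_y);           // recruitment bias-adjustment factors, nyears
  DATA_IVECTOR(fleet_kind);   // per fleet: 0 = fishery, 1 = survey
  DATA_VECTOR(fleet_timing);  // fraction of year at survey observation
  DATA_MATRIX(catch_obs);     // nfishery x nyears observed catch biomass
  DATA_IVECTOR(fishery_idx);  // fishery row -> fleet column (0-based)
  DATA_IVECTOR(iobs_fleet);   // survey-index observations (0-based fleet)
  DATA_IVECTOR(iobs_year);
  DATA_VECTOR(iobs_val);
  DATA_VECTOR(iobs_sd);
  DATA_IVECTOR(ac_fleet);     // age-composition observations
  DATA_IVECTOR(ac_year);
  DATA_VECTOR(ac_N);
  DATA_MATRIX(ac_prop);       // nobs_ac x nages
  DATA_IVECTOR(lc_fleet);     // length-composition observations
  DATA_IVECTOR(lc_year);
  DATA_VECTOR(lc_N);
  DATA_MATRIX(lc_prop);       // nobs_lc x nbins

  PARAMETER(log_R0);
  PARAMETER(log_M);
  PARAMETER(trans_h);         // h = 0.2 + 0.8 / (1 + exp(-trans_h))
  PARAMETER_VECTOR(sel_a50);  // per fleet
  PARAMETER_VECTOR(log_sel_slope);
  PARAMETER_VECTOR(log_q);    // per fleet; used for surveys only
  PARAMETER(log_sigma_R);
  PARAMETER_VECTOR(rec_devs); // nyears

  int na = ages.size();
  int ny = b_y.size();
  int nfleets = fleet_kind.size();
  int nfishery = fishery_idx.size();
  int nbins = alk.rows();

  Type R0 = exp(log_R0);
  Type M = exp(log_M);
  Type h = Type(0.2) + Type(0.8) / (Type(1.0) + exp(-trans_h));
  Type sigma_R = exp(log_sigma_R);

  // Selectivity-at-age per fleet
  matrix<Type> sel(na, nfleets);
  for (int f = 0; f < nfleets; f++) {
    Type slope = exp(log_sel_slope(f));
    for (int a = 0; a < na; a++) {
      sel(a, f) = Type(1.0) / (Type(1.0) + exp(-slope * (ages(a) - sel_a50(f))));
    }
  }

  // Unfished equilibrium and SSB0
  vector<Type> N0(na);
  for (int a = 0; a < na; a++) N0(a) = R0 * exp(-M * ages(a));
  N0(na - 1) = R0 * exp(-M * ages(na - 1)) / (Type(1.0) - exp(-M));
  Type SSB0 = 0;
  for (int a = 0; a < na; a++) SSB0 += N0(a) * w_a(a) * mat_a(a);

  // Annual recursion, conditioning on catch
  matrix<Type> N(na, ny); N.setZero();
  matrix<Type> Z(na, ny);
  matrix<Type> Fm(nfishery, ny); Fm.setZero();
  vector<Type> SSB(ny), R(ny);
  for (int a = 0; a < na; a++) N(a, 0) = N0(a);

  for (int y = 0; y < ny; y++) {
    SSB(y) = 0;
    for (int a = 0; a < na; a++) SSB(y) += N(a, y) * w_a(a) * mat_a(a);
    Type bh = Type(4.0) * h * R0 * SSB(y) /
      (SSB0 * (Type(1.0) - h) + SSB(y) * (Type(5.0) * h - Type(1.0)));
    R(y) = bh * exp(rec_devs(y) - b_y(y) * sigma_R * sigma_R / Type(2.0));
    N(0, y) = R(y);

    // Solve F for each fishery so predicted catch biomass = observed.
    // Gauss-Seidel over fleets (exact Newton when there is one fishery);
    // the Baranov catch is concave increasing in F, so Newton converges
    // monotonically from either side.
    int nsweep = (nfishery > 1) ? 6 : 1;
    for (int sweep = 0; sweep < nsweep; sweep++) {
      for (int fi = 0; fi < nfishery; fi++) {
        int f = fishery_idx(fi);
        Type obs = catch_obs(fi, y);
        if (asDouble(obs) <= 0.0) { Fm(fi, y) = 0; continue; }
        // mortality from other fleets
        vector<Type> otherZ(na);
        for (int a = 0; a < na; a++) {
          otherZ(a) = M;
          for (int gi = 0; gi < nfishery; gi++) {
            if (gi == fi) continue;
            otherZ(a) += sel(a, fishery_idx(gi)) * Fm(gi, y);
          }
        }
        Type Bsel = 0;
        for (int a = 0; a < na; a++) Bsel += sel(a, f) * N(a, y) * w_a(a);
        Type Ff = obs / (Bsel + obs);  // starting exploitation fraction
        for (int it = 0; it < 14; it++) {
          Type C = 0, dC = 0;
          for (int a = 0; a < na; a++) {
            Type u = sel(a, f) * Ff;
            Type Za = otherZ(a) + u;
            Type ez = exp(-Za);
            C += w_a(a) * N(a, y) * (u / Za) * (Type(1.0) - ez);
            dC += w_a(a) * N(a, y) * sel(a, f) *
              (((Za - u) / (Za * Za)) * (Type(1.0) - ez) + (u / Za) * ez);
          }
          Ff = Ff - (C - obs) / dC;
          Ff = CppAD::CondExpLt(Ff, Type(1e-10), Type(1e-10), Ff);
          Ff = CppAD::CondExpGt(Ff, Type(20.0), Type(20.0), Ff);
        }
        Fm(fi, y) = Ff;
      }
    }

    for (int a = 0; a < na; a++) {
      Z(a, y) = M;
      for (int fi = 0; fi < nfishery; fi++) {
        Z(a, y) += sel(a, fishery_idx(fi)) * Fm(fi, y);
      }
    }
    if (y < ny - 1) {
      for (int a = 0; a < na - 1; a++) {
        N(a + 1, y + 1) = N(a, y) * exp(-Z(a, y));
      }
      N(na - 1, y + 1) += N(na - 1, y) * exp(-Z(na - 1, y));
    }
  }

  // Expected observations: per-fleet composition numbers and survey index
  array<Type> comp_num(na, ny, nfleets);
  matrix<Type> pred_index(nfleets, ny); pred_index.setZero();
  for (int f = 0; f < nfleets; f++) {
    if (fleet_kind(f) == 1) {               // survey: numbers at timing
      Type q = exp(log_q(f));
      for (int y = 0; y < ny; y++) {
        Type idx = 0;
        for (int a = 0; a < na; a++) {
          Type avail = sel(a, f) * N(a, y) * exp(-fleet_timing(f) * Z(a, y));
          comp_num(a, y, f) = avail;
          idx += avail * w_a(a);
        }
        pred_index(f, y) = q * idx;
      }
    } else {                                 // fishery: whole-year catch
      int fi = -1;
      for (int gi = 0; gi < nfishery; gi++) if (fishery_idx(gi) == f) fi = gi;
      for (int y = 0; y < ny; y++) {
        for (int a = 0; a < na; a++) {
          Type u = sel(a, f) * Fm(fi, y);
          comp_num(a, y, f) =
            (u / Z(a, y)) * N(a, y) * (Type(1.0) - exp(-Z(a, y)));
        }
      }
    }
  }

  // --- negative log-likelihood ---------------------------------------
  Type nll_index = 0, nll_ac = 0, nll_lc = 0, nll_devs = 0;
  Type tiny = Type(1e-10);

  for (int i = 0; i < iobs_val.size(); i++) {
    Type pred = pred_index(iobs_fleet(i), iobs_year(i));
    Type r = log(iobs_val(i)) - log(pred);
    nll_index += r * r / (Type(2.0) * iobs_sd(i) * iobs_sd(i));
  }

  matrix<Type> ac_pred(ac_N.size(), na);
  for (int i = 0; i < ac_N.size(); i++) {
    int f = ac_fleet(i), y = ac_year(i);
    Type tot = 0;
    for (int a = 0; a < na; a++) tot += comp_num(a, y, f);
    for (int a = 0; a < na; a++) {
      Type p = comp_num(a, y, f) / tot;
      ac_pred(i, a) = p;
      Type psafe = CppAD::CondExpLt(p, tiny, tiny, p);
      nll_ac -= ac_N(i) * ac_prop(i, a) * log(psafe);
    }
  }

  matrix<Type> lc_pred(lc_N.size(), nbins);
  for (int i = 0; i < lc_N.size(); i++) {
    int f = lc_fleet(i), y = lc_year(i);
    vector<Type> lnum(nbins); lnum.setZero();
    Type tot = 0;
    for (int l = 0; l < nbins; l++) {
      for (int a = 0; a < na; a++) lnum(l) += alk(l, a) * comp_num(a, y, f);
      tot += lnum(l);
    }
    for (int l = 0; l < nbins; l++) {
      Type p = lnum(l) / tot;
      lc_pred(i, l) = p;
      Type psafe = CppAD::CondExpLt(p, tiny, tiny, p);
      nll_lc -= lc_N(i) * lc_prop(i, l) * log(psafe);
    }
  }

  // Normal penalty on deviations (the log sigma term matters only when
  // sigma_R is estimated; it is constant otherwise).
  for (int y = 0; y < ny; y++) {
    nll_devs += rec_devs(y) * rec_devs(y) /
      (Type(2.0) * sigma_R * sigma_R) + log_sigma_R;
  }

  Type nll = nll_index + nll_ac + nll_lc + nll_devs;

  vector<Type> F_total(ny); F_total.setZero();
  for (int y = 0; y < ny; y++) {
    for (int fi = 0; fi < nfishery; fi++) F_total(y) += Fm(fi, y);
  }
  Type depletion = SSB(ny - 1) / SSB0;
  Type F_terminal = F_total(ny - 1);

  REPORT(N); REPORT(Z); REPORT(Fm); REPORT(SSB); REPORT(R);
  REPORT(SSB0); REPORT(pred_index); REPORT(sel);
  REPORT(ac_pred); REPORT(lc_pred);
  REPORT(nll_index); REPORT(nll_ac); REPORT(nll_lc); REPORT(nll_devs);
  ADREPORT(M); ADREPORT(h); ADREPORT(R0); ADREPORT(SSB0);
  ADREPORT(SSB); ADREPORT(R); ADREPORT(depletion); ADREPORT(F_terminal);
  return nll;
}
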