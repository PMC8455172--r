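#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Continuous-time exclusion process on a hexagonal lattice with three
// cell-cycle phases (1 = red/G1, 2 = yellow/eS, 3 = green/S/G2/M).
// Event classes per phase p with N_p agents: movement attempts at rate
// N_p * M_p and cycle events at rate N_p * R_p. Waiting times are
// exponential with the total rate; the event class is chosen with
// probability proportional to its rate and the agent uniformly within its
// phase. Movement and division attempts whose target site is occupied or
// out of domain are aborted (time still advances); red->yellow and
// yellow->green transitions are unconditional. Division places a red
// daughter on the chosen neighbour and resets the mother to red.
//
// Rows are spaced delta*sqrt(3)/2 in y; odd rows start at x = 0, even rows
// are offset delta/2, so all six neighbours are exactly delta away. Offsets
// must match neighbour_offsets() on the R side.

static const int DI[6] = {0, 0, -1, -1, 1, 1};
static const int DJ_ODD[6] = {-1, 1, -1, 0, -1, 0};
static const int DJ_EVEN[6] = {-1, 1, 0, 1, 0, 1};

struct PhaseList {
  std::vector<int> members;          // agent indices (0-based)
  void add(std::vector<int> &pos, int a) {
    pos[a] = (int)members.size();
    members.push_back(a);
  }
  void remove(std::vector<int> &pos, int a) {
    int k = pos[a];
    int last = members.back();
    members[k] = last;
    pos[last] = k;
    members.pop_back();
    pos[a] = -1;
  }
};

// [[Rcpp::export]]
List sim_core(IntegerVector row0, IntegerVector col0, IntegerVector phase0,
              NumericVector motility, NumericVector transition,
              int n_rows, int n_cols, double duration,
              IntegerVector tracked_ids, double max_events,
              bool record_initial, bool record_traj = true) {
  const int n0 = row0.size();
  std::vector<int> row(row0.begin(), row0.end());
  std::vector<int> col(col0.begin(), col0.end());
  std::vector<int> phase(phase0.begin(), phase0.end());

  std::vector<int> occ((size_t)n_rows * n_cols, 0);   // 0 = empty, else id
  auto cell = [&](int i, int j) -> int & {
    return occ[(size_t)(i - 1) * n_cols + (j - 1)];
  };
  for (int a = 0; a < n0; ++a) {
    if (row[a] < 1 || row[a] > n_rows || col[a] < 1 || col[a] > n_cols)
      stop("sim_core: agent outside lattice domain");
    int &site = cell(row[a], col[a]);
    if (site != 0) stop("sim_core: two agents share a lattice site");
    site = a + 1;
  }

  PhaseList plist[3];
  std::vector<int> pos(n0, -1);
  for (int a = 0; a < n0; ++a) {
    if (phase[a] < 1 || phase[a] > 3) stop("sim_core: invalid phase code");
    plist[phase[a] - 1].add(pos, a);
  }

  std::vector<char> is_tracked(n0, 0), terminated(n0, 0);
  std::vector<int> tslot(n0, -1);         // agent -> index into tracked_ids
  for (int k = 0; k < tracked_ids.size(); ++k) {
    int id = tracked_ids[k];
    if (id < 1 || id > n0) stop("sim_core: tracked id out of range");
    is_tracked[id - 1] = 1;
    tslot[id - 1] = k;
  }
  // successful moves per tracked cell while in each phase (path length is
  // moves * delta since all neighbour steps have equal length)
  NumericMatrix tracked_moves(3, tracked_ids.size());

  // trajectory log: id, time, row, col, phase
  std::vector<int> tr_id, tr_row, tr_col, tr_phase;
  std::vector<double> tr_t;
  auto log_event = [&](int a, double t) {
    if (!record_traj) return;
    tr_id.push_back(a + 1);
    tr_t.push_back(t);
    tr_row.push_back(row[a]);
    tr_col.push_back(col[a]);
    tr_phase.push_back(phase[a]);
  };
  if (record_initial) {
    for (int a = 0; a < n0; ++a) if (is_tracked[a]) log_event(a, 0.0);
  }

  const double M[3] = {motility[0], motility[1], motility[2]};
  const double R[3] = {transition[0], transition[1], transition[2]};

  double t = 0.0;
  double n_events = 0.0;
  // counters: move ok, move aborted, r->y, y->g, division ok, division aborted
  double cnt[6] = {0, 0, 0, 0, 0, 0};
  int last_event = -1;     // index into cnt of the last applied event
  double last_dt = NA_REAL;
  bool exhausted = false;  // total rate hit zero

  RNGScope scope;

  while (true) {
    double np[3] = {(double)plist[0].members.size(),
                    (double)plist[1].members.size(),
                    (double)plist[2].members.size()};
    double rate[6];
    double lambda = 0.0;
    for (int p = 0; p < 3; ++p) {
      rate[p] = np[p] * M[p];          // movement attempt, phase p
      rate[3 + p] = np[p] * R[p];      // cycle event, phase p
      lambda += rate[p] + rate[3 + p];
    }
    if (lambda <= 0.0) { exhausted = true; t = duration; break; }

    double dt = exp_rand() / lambda;
    if (t + dt > duration) { t = duration; break; }
    t += dt;
    last_dt = dt;

    // choose event class proportional to rate, then agent uniformly
    double u = unif_rand() * lambda;
    int cls = 0;
    for (; cls < 5; ++cls) {
      if (u < rate[cls]) break;
      u -= rate[cls];
    }
    int p = cls % 3;
    int k = (int)(unif_rand() * plist[p].members.size());
    if (k >= (int)plist[p].members.size()) k = (int)plist[p].members.size() - 1;
    int a = plist[p].members[k];

    if (cls < 3) {
      // movement attempt: uniform over the six directions
      int dir = (int)(unif_rand() * 6.0); if (dir > 5) dir = 5;
      int ni = row[a] + DI[dir];
      int nj = col[a] + (row[a] % 2 == 0 ? DJ_EVEN[dir] : DJ_ODD[dir]);
      bool ok = ni >= 1 && ni <= n_rows && nj >= 1 && nj <= n_cols &&
                cell(ni, nj) == 0;
      if (ok) {
        cell(row[a], col[a]) = 0;
        row[a] = ni; col[a] = nj;
        cell(ni, nj) = a + 1;
        cnt[0] += 1; last_event = 0;
        if (a < (int)is_tracked.size() && is_tracked[a] && !terminated[a]) {
          tracked_moves(p, tslot[a]) += 1;
          log_event(a, t);
        }
      } else {
        cnt[1] += 1; last_event = 1;
      }
    } else if (p == 0) {
      // red -> yellow, unconditional
      plist[0].remove(pos, a);
      phase[a] = 2;
      plist[1].add(pos, a);
      cnt[2] += 1; last_event = 2;
      if (a < (int)is_tracked.size() && is_tracked[a] && !terminated[a])
        log_event(a, t);
    } else if (p == 1) {
      // yellow -> green, unconditional
      plist[1].remove(pos, a);
      phase[a] = 3;
      plist[2].add(pos, a);
      cnt[3] += 1; last_event = 3;
      if (a < (int)is_tracked.size() && is_tracked[a] && !terminated[a])
        log_event(a, t);
    } else {
      // green -> division: red daughter on a uniformly chosen neighbour,
      // aborted entirely if that site is occupied or out of domain
      int dir = (int)(unif_rand() * 6.0); if (dir > 5) dir = 5;
      int ni = row[a] + DI[dir];
      int nj = col[a] + (row[a] % 2 == 0 ? DJ_EVEN[dir] : DJ_ODD[dir]);
      bool ok = ni >= 1 && ni <= n_rows && nj >= 1 && nj <= n_cols &&
                cell(ni, nj) == 0;
      if (ok) {
        plist[2].remove(pos, a);
        phase[a] = 1;                 // mother returns to red in place
        plist[0].add(pos, a);
        int b = (int)row.size();      // daughter agent
        row.push_back(ni); col.push_back(nj); phase.push_back(1);
        pos.push_back(-1);
        plist[0].add(pos, b);
        cell(ni, nj) = b + 1;
        cnt[4] += 1; last_event = 4;
        if (a < (int)is_tracked.size() && is_tracked[a] && !terminated[a]) {
          // tracking ends when the cell returns to its initial (red) phase
          log_event(a, t);
          terminated[a] = 1;
        }
      } else {
        cnt[5] += 1; last_event = 5;
      }
    }

    n_events += 1.0;
    if (max_events >= 0 && n_events >= max_events) break;
  }

  IntegerVector term(tracked_ids.size());
  for (int k = 0; k < tracked_ids.size(); ++k) {
    int a = tracked_ids[k] - 1;
    term[k] = (a < (int)terminated.size() && terminated[a]) ? 1 : 0;
  }

  return List::create(
    _["row"] = wrap(row), _["col"] = wrap(col), _["phase"] = wrap(phase),
    _["time"] = t,
    _["n_events"] = n_events,
    _["counts"] = NumericVector::create(
      _["move_success"] = cnt[0], _["move_aborted"] = cnt[1],
      _["red_to_yellow"] = cnt[2], _["yellow_to_green"] = cnt[3],
      _["division_success"] = cnt[4], _["division_aborted"] = cnt[5]),
    _["last_event"] = last_event + 1,   // 1-based, 0 if none
    _["last_dt"] = last_dt,
    _["exhausted"] = exhausted,
    _["traj_id"] = wrap(tr_id), _["traj_t"] = wrap(tr_t),
    _["traj_row"] = wrap(tr_row), _["traj_col"] = wrap(tr_col),
    _["traj_phase"] = wrap(tr_phase),
    _["tracked_moves"] = tracked_moves,
    _["tracked_divided"] = term);
}
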