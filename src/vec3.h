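#ifndef CELLFLOW_VEC3_H
#define CELLFLOW_VEC3_H

#include <cmath>

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};

inline V3 operator+(const V3 &a, const V3 &b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline V3 operator-(const V3 &a, const V3 &b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline V3 operator*(double s, const V3 &a) { return V3(s * a.x, s * a.y, s * a.z); }
inline V3 operator*(const V3 &a, double s) { return s * a; }
inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3 &a, const V3 &b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }
inline double norm2(const V3 &a) { return dot(a, a); }

#endif
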