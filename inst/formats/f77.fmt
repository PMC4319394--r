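# FORTRAN 77 export format (fixed form, 72-column limit)
name = f77
comment = C
assign = =
terminator =
index_base = 1
block_style = f77
piecewise = call
max_line = 72
continuation =      &
bool.true = .TRUE.
bool.false = .FALSE.
pi = 3.141592653589793D0
nan = 0.0D0
array.constants = CONSTS({i})
array.states = STATES({i})
array.rates = RATES({i})
array.algebraic = ALGBRC({i})
scalar.voi = VOI
op.plus = infix +
op.minus = infix -
op.times = infix *
op.divide = infix /
op.power = infix **
op.root = call SQRT
op.exp = call EXP
op.ln = call LOG
op.log = call LOG10
op.abs = call ABS
op.floor = call FLOOR
op.ceiling = call CEILING
op.sin = call SIN
op.cos = call COS
op.tan = call TAN
op.arcsin = call ASIN
op.arccos = call ACOS
op.arctan = call ATAN
op.and = infix .AND.
op.or = infix .OR.
op.not = prefix .NOT.
op.eq = infix .EQ.
op.neq = infix .NE.
op.lt = infix .LT.
op.leq = infix .LE.
op.gt = infix .GT.
op.geq = infix .GE.
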