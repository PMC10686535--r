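a
an
the
is
are
was
were
in
at
on
of
with
and
or
no
not
there
this
that
to
for
by
from
as
be
been
which
into
within
along
near
about
since
versus
seen
noted
present
identified
demonstrated
measuring
consistent
suggestive
compatible
considered
favored
again
also
now
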