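variable_key,span_start,span_end,release_year
AUX,1999,2000,2001
AUX,2001,2002,2003
AUX,2003,2004,2005
AUX,2005,2006,2007
AUX,2007,2008,2009
AUX,2009,2010,2011
AUX,2011,2012,2013
AUX,2013,2014,2015
AUX,2015,2016,2017
AUX,2017,2020,2021
BMXBMI,1999,2000,2001
BMXBMI,2001,2002,2003
BMXBMI,2003,2004,2005
BMXBMI,2005,2006,2007
BMXBMI,2007,2008,2009
BMXBMI,2009,2010,2011
BMXBMI,2011,2012,2013
BMXBMI,2013,2014,2015
BMXBMI,2015,2016,2017
BMXBMI,2017,2020,2021
DED061,2001,2002,2003
DED061,2003,2004,2005
DED061,2005,2006,2007
DIQ,1999,2000,2001
DIQ,2001,2002,2003
DIQ,2003,2004,2005
DIQ,2005,2006,2007
DIQ,2007,2008,2009
DIQ,2009,2010,2011
DIQ,2011,2012,2013
DIQ,2013,2014,2015
DIQ,2015,2016,2017
DIQ,2017,2020,2021
KIQ026,2007,2008,2009
KIQ026,2009,2010,2011
KIQ026,2011,2012,2013
KIQ026,2013,2014,2015
KIQ026,2015,2016,2017
KIQ026,2017,2020,2021
KIQ480,2005,2006,2007
KIQ480,2007,2008,2009
KIQ480,2009,2010,2011
KIQ480,2011,2012,2013
KIQ480,2013,2014,2015
KIQ480,2015,2016,2017
KIQ480,2017,2020,2021
LBXFER,1999,2000,2001
LBXFER,2001,2002,2003
LBXFER,2005,2006,2007
LBXFER,2007,2008,2009
LBXFER,2009,2010,2011
LBXFER,2015,2016,2017
LBXFER,2017,2020,2021
LBXSAPSI,2003,2004,2005
LBXSAPSI,2005,2006,2007
LBXSAPSI,2007,2008,2009
LBXSAPSI,2009,2010,2011
LBXSAPSI,2011,2012,2013
LBXSAPSI,2013,2014,2015
LBXSAPSI,2015,2016,2017
LBXSAPSI,2017,2020,2021
LBXSASSI,1999,2000,2001
LBXSASSI,2001,2002,2003
LBXSASSI,2003,2004,2005
LBXSASSI,2005,2006,2007
LBXSASSI,2007,2008,2009
LBXSASSI,2009,2010,2011
LBXSASSI,2011,2012,2013
LBXSASSI,2013,2014,2015
LBXSASSI,2015,2016,2017
LBXSASSI,2017,2020,2021
LBXSATSI,1999,2000,2001
LBXSATSI,2001,2002,2003
LBXSATSI,2003,2004,2005
LBXSATSI,2005,2006,2007
LBXSATSI,2007,2008,2009
LBXSATSI,2009,2010,2011
LBXSATSI,2011,2012,2013
LBXSATSI,2013,2014,2015
LBXSATSI,2015,2016,2017
LBXSATSI,2017,2020,2021
LBXSGTSI,1999,2000,2001
LBXSGTSI,2001,2002,2003
LBXSGTSI,2003,2004,2005
LBXSGTSI,2005,2006,2007
LBXSGTSI,2007,2008,2009
LBXSGTSI,2009,2010,2011
LBXSGTSI,2011,2012,2013
LBXSGTSI,2013,2014,2015
LBXSGTSI,2015,2016,2017
LBXSGTSI,2017,2020,2021
MCQ010,2001,2002,2003
MCQ010,2003,2004,2005
MCQ010,2005,2006,2007
MCQ010,2007,2008,2009
MCQ010,2009,2010,2011
MCQ010,2011,2012,2013
MCQ010,2013,2014,2015
MCQ010,2015,2016,2017
MCQ010,2017,2020,2021
MCQ160F,1999,2000,2001
MCQ160F,2001,2002,2003
MCQ160F,2003,2004,2005
MCQ160F,2005,2006,2007
MCQ160F,2007,2008,2009
MCQ160F,2009,2010,2011
MCQ160F,2011,2012,2013
MCQ160F,2013,2014,2015
MCQ160F,2015,2016,2017
MCQ160F,2017,2020,2021
MCQ160G,2011,2012,2013
MCQ160G,2013,2014,2015
MCQ160G,2015,2016,2017
MCQ160G,2017,2020,2021
SSSNFL,2013,2014,2015
TCHOL,1999,2000,2001
TCHOL,2001,2002,2003
TCHOL,2003,2004,2005
TCHOL,2005,2006,2007
TCHOL,2007,2008,2009
TCHOL,2009,2010,2011
TCHOL,2011,2012,2013
TCHOL,2013,2014,2015
TCHOL,2015,2016,2017
TCHOL,2017,2020,2021
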